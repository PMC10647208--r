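# Primer alignment and amplification simulation.

test_that("reverse complement is IUPAC-aware and involutive", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  # hand-computed with the IUPAC complement table: C->G, C->G, G->C, Y->R,
  # C->G, A->T, A->T, T->A, T->A, Y->R, M->K, T->A, T->A, T->A, R->Y, A->T,
  # G->C, T->A, T->A, T->A, then reversed
  expect_identical(reverse_complement("CCGYCAATTYMTTTRAGTTT"),
                   "AAACTYAAAKRAATTGRCGG")
  set.seed(42)
  for (k in 1:20) {
    x <- random_primer(sample(10:30, 1), n_degenerate = sample(0:4, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
  expect_error(reverse_complement("ACXGT"), "position 3")
})

test_that("alignment scores match spec'd small cases", {
  h <- align_primer("ACGT", "TTACGTAA")
  expect_equal(h$score, 4)
  expect_equal(h$start, 2)
  expect_equal(h$end, 6)
  expect_identical(h$columns, rep("match", 4))

  # one mismatch, no gaps, beats any gapped alternative under the scheme
  h2 <- align_primer("ACGT", "TTACCTAA")
  expect_equal(h2$score, 3)

  # primer ambiguity expands to a match set: Y matches C
  h3 <- align_primer("AYGT", "TTACGTAA")
  expect_equal(h3$score, 4)

  # ambiguity in the template scores as mismatch, never as match
  h4 <- align_primer("ACGT", "TTACNTAA")
  expect_equal(h4$score, 3)
})

test_that("DP oracle agrees with exhaustive enumeration on tiny instances", {
  set.seed(11)
  for (k in 1:40) {
    primer <- random_primer(sample(2:4, 1), n_degenerate = sample(0:1, 1))
    template <- random_template(sample(2:6, 1))
    expect_equal(oracle_score(primer, template),
                 enum_score(primer, template),
                 info = paste(primer, template))
  }
})

test_that("gap run scoring is affine: open -1, extend -0.5 per extra column", {
  # primer needs a 2-column gap in the template to align both halves exactly
  # AAAACCCC vs AAAA|GG|CCCC: 8 matches - (1 + 0.5) = 6.5 when deleting GG
  h <- align_primer("AAAATTTT", "AAAAGGTTTT")
  # alternatives: ungapped 8-vs-8 window has at most 6 matches -> 6.0
  expect_equal(h$score, 6.5)
})

test_that("equal-score hits resolve to the smallest start deterministically", {
  h <- align_primer("ACGT", "ACGTTTACGT")
  expect_equal(h$score, 4)
  expect_equal(h$start, 0)
  expect_equal(h$end, 4)
})

test_that("simulate_pcr extracts the planted insert", {
  p <- test_primers(threshold = 1)
  tmpl <- planted_template("TTTTGGGGCCCC", p)
  amp <- simulate_pcr(tmpl, p)
  expect_identical(amp$sequence, "TTTTGGGGCCCC")
  expect_identical(amp$strand, "+")
  expect_false(amp$includes_primers)

  pk <- test_primers(threshold = 1, keep_primers = TRUE)
  ampk <- simulate_pcr(tmpl, pk)
  expect_identical(ampk$sequence,
                   paste0(pk$forward, "TTTTGGGGCCCC",
                          reverse_complement(pk$reverse)))
  # with primers kept, the amplicon's head realigns to the forward primer at
  # the hit's own score
  expect_equal(align_primer(pk$forward, ampk$sequence)$score,
               ampk$fwd_hit$score)
})

test_that("minus-strand deposits are recovered, and the scan can be disabled", {
  p <- test_primers(threshold = 1)
  tmpl <- planted_template("TTTTGGGGCCCC", p)
  amp <- simulate_pcr(reverse_complement(tmpl), p)
  expect_identical(amp$sequence, "TTTTGGGGCCCC")
  expect_identical(amp$strand, "-")
  expect_null(simulate_pcr(reverse_complement(tmpl), p,
                           try_reverse_strand = FALSE))
})

test_that("a 3'-end mismatch vetoes the amplicon even above threshold", {
  p <- test_primers(threshold = 0.8)
  fwd <- p$forward
  # mutate the last base of the planted forward site (G -> A mismatches G)
  site <- fwd
  substr(site, nchar(site), nchar(site)) <- "A"
  tmpl <- paste0("AAAAAAAA", site, "TTTTGGGGCCCC",
                 reverse_complement(p$reverse), "TTTTTTTT")
  expect_null(simulate_pcr(tmpl, p))
})

test_that("threshold is a fraction of primer length", {
  # one internal mismatch in the 20-nt forward site: score 19/20 = 0.95
  base <- test_primers()
  site <- base$forward
  substr(site, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site, 10, 10))[1]
  tmpl <- paste0("AAAAAAAA", site, "TTTTGGGGCCCC",
                 reverse_complement(base$reverse), "TTTTTTTT")
  p90 <- test_primers(threshold = 0.9)
  amp <- simulate_pcr(tmpl, p90)
  expect_identical(amp$sequence, "TTTTGGGGCCCC")
  expect_equal(amp$fwd_hit$score, 19)
  p97 <- test_primers(threshold = 0.97)
  expect_null(simulate_pcr(tmpl, p97))
})

test_that("raising the threshold never gains amplicons (monotonicity)", {
  set.seed(23)
  p_seq <- "CCGGTCACTTGATCTACCAG"
  r_seq <- "ATGACGGTGACATAGTAGCG"
  templates <- replicate(30, {
    ins <- random_template(40)
    tm <- paste0(random_template(10),
                 template_with_site(p_seq, 20, n_mut = sample(0:3, 1)),
                 ins,
                 template_with_site(
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(r_seq))), 20,
                   n_mut = sample(0:3, 1)),
                 random_template(10))
    tm
  })
  prev <- rep(TRUE, length(templates))
  for (thr in c(0.7, 0.85, 0.95, 1)) {
    p <- primer_pair(p_seq, r_seq, threshold = thr)
    now <- vapply(templates,
                  function(tm) !is.null(simulate_pcr(tm, p)), logical(1))
    expect_true(all(now <= prev), info = paste("threshold", thr))
    prev <- now
  }
})

test_that("abutting primers with no insert yield nothing", {
  p <- test_primers(threshold = 1)
  tmpl <- paste0("AAAAAAAA", p$forward, reverse_complement(p$reverse),
                 "TTTTTTTT")
  expect_null(simulate_pcr(tmpl, p))
  pk <- test_primers(threshold = 1, keep_primers = TRUE)
  amp <- simulate_pcr(tmpl, pk)
  expect_identical(amp$sequence,
                   paste0(pk$forward, reverse_complement(pk$reverse)))
})

test_that("primer presets carry the shipped sequences and validate", {
  presets <- primer_presets()
  expect_setequal(names(presets),
                  c("515FB", "926R", "BITS", "B58S3", "Fa-150", "Ra-2"))
  p <- resolve_primers("515FB", "926R")
  expect_identical(p$forward, "GTGYCAGCMGCCGCGGTAA")
  expect_identical(p$reverse, "CCGYCAATTYMTTTRAGTTT")
  expect_error(primer_pair("ACGT", "ACGTACGTAC"), "at least 10")
  expect_error(primer_pair("ACGTACGTAC", "ACGTACGTAC", threshold = 1.2))
})
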