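# Database construction, taxonomy filtering, SA grouping, merging, summary.

test_that("build collapses identical amplicons and accumulates taxa", {
  p <- test_primers(threshold = 1)
  s1 <- planted_template("AAACCCGGGTTTAAACCCGG", p)
  s2 <- planted_template("TTTGGGCCCAAATTTGGGCC", p)
  rec <- record_table(
    c("R1", "R2", "R3"),
    c("Fusarium oxysporum", "Fusarium solani", "Fusarium graminearum"),
    c(s1, s1, s2))
  db <- build_database(rec, "Fusarium", p)
  expect_equal(nrow(db$entries), 2)
  i1 <- which(db$entries$sequence == "AAACCCGGGTTTAAACCCGG")
  expect_setequal(db$entries$taxa[[i1]],
                  c("Fusarium oxysporum", "Fusarium solani"))
  i2 <- which(db$entries$sequence == "TTTGGGCCCAAATTTGGGCC")
  expect_identical(db$entries$taxa[[i2]], "Fusarium graminearum")
})

test_that("redundant amplicons (same species, same sequence) collapse", {
  p <- test_primers(threshold = 1)
  s1 <- planted_template("AAACCCGGGTTTAAACCCGG", p)
  rec <- record_table(c("R1", "R2"),
                      c("Fusarium solani", "Fusarium solani"),
                      c(s1, s1))
  db <- build_database(rec, "Fusarium", p)
  expect_equal(nrow(db$entries), 1)
  expect_identical(db$entries$taxa[[1]], "Fusarium solani")
  expect_setequal(db$entries$accessions[[1]], c("R1", "R2"))
})

test_that("off-genus records are excluded and counted", {
  p <- test_primers(threshold = 1)
  rec <- record_table(
    c("R1", "R2"),
    c("Fusarium solani", "Alternaria alternata"),
    c(planted_template("AAACCCGGGTTTAAACCCGG", p),
      planted_template("TTTGGGCCCAAATTTGGGCC", p)))
  db <- build_database(rec, "fusarium  ", p)  # case/space-insensitive match
  expect_equal(nrow(db$entries), 1)
  expect_equal(db$filter_log$build$n_wrong_genus, 1)
})

test_that("zero amplifiable records give an empty database, not an error", {
  p <- test_primers(threshold = 1)
  rec <- record_table("R1", "Fusarium solani",
                      paste(rep("ACGT", 30), collapse = ""))
  expect_message(db <- build_database(rec, "Fusarium", p),
                 "no amplifiable")
  expect_equal(nrow(db$entries), 0)
  expect_equal(db$filter_log$build$n_no_amplicon, 1)
})

test_that("taxonomy filter removes labels, then empty entries", {
  db <- asv_db("Fusarium",
               sequences = c("ACGT", "GGTT"),
               taxa = list(c("Fusarium sp.", "Fusarium solani"),
                           "Fusarium sp."))
  out <- filter_taxa(db)
  expect_equal(nrow(out$entries), 1)
  expect_identical(out$entries$taxa[[1]], "Fusarium solani")
  expect_equal(out$filter_log$taxa_filter$entries_removed, 1)
  expect_equal(out$filter_log$taxa_filter$removed_taxa[["^\\S+ sp\\.$"]], 2)
  # aff. and cf. epithets are filtered by default too
  db2 <- asv_db("Fusarium", sequences = "AAAA",
                taxa = list(c("Fusarium aff. solani", "Fusarium cf. solani",
                              "Fusarium solani")))
  expect_identical(filter_taxa(db2)$entries$taxa[[1]], "Fusarium solani")
  # empty pattern list is the identity
  expect_identical(filter_taxa(db, character()), db)
})

test_that("SA naming: SA-form iff >=2 taxa, numbered in sequence order", {
  db <- make_sa_groups(asv_db(
    "Fusarium",
    sequences = c("TTTT", "AAAA", "CCCC"),
    taxa = list(c("Fusarium a", "Fusarium b"),
                "Fusarium c",
                c("Fusarium d", "Fusarium e", "Fusarium f"))))
  # entries reordered canonically: AAAA, CCCC, TTTT
  expect_identical(db$entries$sequence, c("AAAA", "CCCC", "TTTT"))
  expect_identical(db$entries$assigned_name,
                   c("Fusarium_c", "Fusarium_SA1", "Fusarium_SA2"))
  expect_identical(db$sa_groups$n, 1:2)
  expect_identical(db$sa_groups$sequence, c("CCCC", "TTTT"))
  expect_setequal(db$sa_groups$members[[1]],
                  c("Fusarium d", "Fusarium e", "Fusarium f"))
})

test_that("species-complex labels stay one taxon with 'complex' preserved", {
  db <- make_sa_groups(asv_db(
    "Fusarium",
    sequences = c("AAAA", "CCCC"),
    taxa = list("Fusarium tricinctum complex",
                c("Fusarium incarnatum-equiseti complex",
                  "Fusarium sporotrichioides"))))
  expect_identical(db$entries$assigned_name[1],
                   "Fusarium_tricinctum_complex")
  # a complex sharing an amplicon with a species forms a 2-member SA group
  expect_identical(db$entries$assigned_name[2], "Fusarium_SA1")
  expect_equal(length(db$sa_groups$members[[1]]), 2)
  s <- db_summary(db)
  expect_equal(s$complex_variants, 1)
  expect_equal(s$sa_variants, 1)
})

test_that("merge unions taxa into new SA groups and drops duplicates", {
  a <- make_sa_groups(asv_db("Fusarium", "ACGT", list("Fusarium x")))
  b <- make_sa_groups(asv_db("Fusarium", "ACGT", list("Fusarium y")))
  m <- merge_databases(a, b)
  expect_equal(nrow(m$entries), 1)
  expect_identical(m$entries$assigned_name, "Fusarium_SA1")
  expect_setequal(m$sa_groups$members[[1]], c("Fusarium x", "Fusarium y"))

  dup <- merge_databases(a, a)
  expect_equal(nrow(dup$entries), 1)
  expect_identical(dup$entries$assigned_name, "Fusarium_x")
  expect_equal(nrow(dup$sa_groups), 0)
})

test_that("merge requires matching genus", {
  a <- asv_db("Fusarium", "ACGT", list("Fusarium x"))
  b <- asv_db("Alternaria", "ACGT", list("Alternaria y"))
  expect_error(merge_databases(a, b), "Fusarium.*Alternaria")
})

test_that("merge is commutative and idempotent on canonical content", {
  set.seed(5)
  seqs1 <- vapply(1:6, function(i) random_template(30), character(1))
  seqs2 <- c(seqs1[1:2], vapply(1:4, function(i) random_template(30),
                                character(1)))
  a <- make_sa_groups(asv_db("Fusarium", seqs1,
                             lapply(1:6, function(i)
                               paste("Fusarium", letters[i]))))
  b <- make_sa_groups(asv_db("Fusarium", seqs2,
                             lapply(1:6, function(i)
                               paste("Fusarium", letters[i + 3]))))
  expect_identical(db_canonical(merge_databases(a, b)),
                   db_canonical(merge_databases(b, a)))
  expect_identical(db_canonical(merge_databases(a, a)), db_canonical(a))
})

test_that("summary counts variants, taxa and attributions", {
  db <- make_sa_groups(asv_db(
    "G",
    sequences = c("AAAA", "CCCC", "GGGG"),
    taxa = list(c("G a", "G b"), "G c", "G x complex")))
  s <- db_summary(db)
  expect_equal(s$total_variants, 3)
  expect_equal(s$sa_variants, 1)
  expect_equal(s$complex_variants, 1)
  expect_equal(s$unique_species_taxa, 2)
  expect_equal(s$sa_taxa, 1)
  expect_equal(s$attributions, 3)

  empty <- asv_db("G")
  s0 <- db_summary(empty)
  expect_true(all(unlist(s0) == 0))
})

test_that("database JSON document round-trips", {
  db <- make_sa_groups(asv_db(
    "Fusarium",
    sequences = c("ACGT", "GGTTCC"),
    taxa = list("Fusarium oxysporum",
                c("Fusarium solani", "Fusarium graminearum")),
    accessions = list("A1", c("A2", "A3")),
    lineage = c("Fungi", "Ascomycota"),
    provenance = list(list(action = "build", genus = "Fusarium"))))
  f <- tempfile(fileext = ".json")
  write_db(db, f)
  back <- read_db(f)
  expect_identical(db_canonical(back), db_canonical(db))
  expect_identical(back$genus, "Fusarium")
  expect_identical(back$lineage, c("Fungi", "Ascomycota"))
})
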