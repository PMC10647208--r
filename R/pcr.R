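# Simulated PCR: primer pairs, glocal primer alignment, amplicon extraction.

#' Construct a primer pair
#'
#' A primer pair bundles the forward and reverse primer (written 5'->3' as on
#' an order sheet, IUPAC ambiguity codes allowed), the score threshold used to
#' accept a binding site, and whether extracted amplicons keep the primer
#' sequences.
#'
#' The threshold is a fraction of the primer's maximum possible alignment
#' score, which equals its length under the scoring scheme (match +1,
#' mismatch 0, gap open -1, gap extend -0.5). A fraction is used rather than
#' an absolute score so the same setting is comparable across primers of
#' different lengths. The default of 0.9 tolerates roughly two internal
#' mismatches on a 20-mer.
#'
#' @param forward,reverse IUPAC nucleotide strings, length >= 10.
#' @param threshold score fraction in `[0, 1]` each primer alignment must
#'   reach, as a fraction of primer length.
#' @param keep_primers if `TRUE`, amplicons span the primer sites; if `FALSE`
#'   (default) only the insert between them is extracted.
#' @return an object of class `primer_pair`.
#' @examples
#' primer_pair("GTGYCAGCMGCCGCGGTAA", "CCGYCAATTYMTTTRAGTTT")
#' @export
primer_pair <- function(forward, reverse, threshold = 0.9,
                        keep_primers = FALSE) {
  forward <- validate_iupac(forward, "forward primer")
  reverse <- validate_iupac(reverse, "reverse primer")
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    stop("primers must be at least 10 nt long", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1,
            is.logical(keep_primers), length(keep_primers) == 1L)
  structure(list(forward = forward, reverse = reverse,
                 threshold = threshold, keep_primers = keep_primers),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair>\n",
      " forward: ", x$forward, " (", nchar(x$forward), " nt)\n",
      " reverse: ", x$reverse, " (", nchar(x$reverse), " nt)\n",
      " threshold: ", x$threshold, "   keep_primers: ", x$keep_primers, "\n",
      sep = "")
  invisible(x)
}

#' Shipped primer presets
#'
#' Returns the named primer sequences shipped with the package (515FB/926R
#' for the bacterial 16S V4V5 region, BITS/B58S3 for the fungal ITS1 region,
#' Fa-150/Ra-2 for the Fusarium elongation factor 1-alpha gene).
#'
#' @return named character vector of primer sequences.
#' @examples
#' primer_presets()[["Fa-150"]]
#' @export
primer_presets <- function() {
  path <- system.file("extdata", "primer_presets.yml", package = "asvrefdb",
                      mustWork = TRUE)
  unlist(yaml::read_yaml(path))
}

#' Resolve a primer-pair specification
#'
#' Accepts either two preset names (see [primer_presets()]) or two explicit
#' IUPAC sequences, in any mix.
#'
#' @param forward,reverse preset name or IUPAC sequence.
#' @inheritParams primer_pair
#' @return a `primer_pair`.
#' @export
resolve_primers <- function(forward, reverse, threshold = 0.9,
                            keep_primers = FALSE) {
  presets <- primer_presets()
  lookup <- function(x) {
    if (x %in% names(presets)) presets[[x]] else x
  }
  primer_pair(lookup(forward), lookup(reverse), threshold = threshold,
              keep_primers = keep_primers)
}

#' Align a primer to a template
#'
#' Finds the best-scoring glocal alignment (the whole primer against a local
#' template window) under affine gap scoring: match +1, mismatch 0, gap open
#' -1, gap extend -0.5 (the open penalty applies to the first column of a gap
#' run, the extend penalty to each subsequent column). An IUPAC ambiguity
#' code in the primer matches any template base in its expansion set; an
#' ambiguous template base (e.g. N) always scores as a mismatch, so that
#' N-rich reference stretches do not amplify spuriously. Equal-score hits are
#' resolved deterministically: smallest start, then shortest span.
#'
#' @param primer IUPAC nucleotide string.
#' @param template nucleotide string (A/C/G/T plus ambiguity codes).
#' @return an `alignment_hit`: list with `score`, `start`/`end` (0-based
#'   half-open template coordinates) and `columns`, the per-column
#'   classification over `match`, `mismatch`, `gap_primer` ('-' placed in the
#'   primer) and `gap_template` ('-' placed in the template), ordered 5'->3'
#'   along the primer.
#' @examples
#' align_primer("ACGT", "TTACGTAA")
#' @export
align_primer <- function(primer, template) {
  primer <- validate_iupac(primer, "primer")
  template <- validate_iupac(template, "template")
  if (nchar(template) == 0L) stop("empty template", call. = FALSE)
  raw <- .align_primer_cpp(primer, template)
  cols <- c("match", "mismatch", "gap_primer", "gap_template")
  structure(list(score = raw$score, start = raw$start, end = raw$end,
                 columns = cols[raw$col_codes + 1L]),
            class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("<alignment_hit> score %.1f at [%d, %d): %s\n",
              x$score, x$start, x$end, paste(x$columns, collapse = ",")))
  invisible(x)
}

# does a hit satisfy the 3'-anchor rule? For the forward primer the 3' end is
# the last three alignment columns; for the reverse primer (aligned as its
# reverse complement, template orientation) it is the first three columns.
anchor_ok <- function(hit, side = c("last", "first")) {
  side <- match.arg(side)
  cols <- hit$columns
  if (length(cols) < 3L) return(FALSE)
  sel <- if (side == "last") utils::tail(cols, 3L) else utils::head(cols, 3L)
  all(sel == "match")
}

#' Simulate PCR amplification on one sequence
#'
#' Mimics primer annealing and extension: the forward primer is aligned to
#' the template, then the reverse complement of the reverse primer is aligned
#' downstream of the forward hit. An amplicon is produced only if both
#' alignments reach `threshold * primer length` and the last three bases at
#' each primer's 3' end align without mismatch or gap (the 3'-anchor rule,
#' mirroring the polymerase's extension requirement). By default both strands
#' are scanned: if the forward orientation yields nothing, the reverse
#' complement of the template is tried, since public-database entries are
#' deposited in either orientation.
#'
#' @param sequence template nucleotide string (typically one source record's
#'   sequence, already uppercased with U normalized to T).
#' @param primers a [primer_pair()].
#' @param try_reverse_strand also scan the reverse complement of the template
#'   when the forward pass fails (default `TRUE`).
#' @return an `amplicon` (list with `sequence`, `start`, `end` 0-based
#'   half-open coordinates on the oriented template, `strand` ("+" or "-"),
#'   `includes_primers`, `fwd_hit`, `rev_hit`), or `NULL` when no valid
#'   amplicon exists.
#' @examples
#' p <- primer_pair("ACGTACGTAC", "GGTTGGTTGG", threshold = 1)
#' tmpl <- paste0("AAAA", "ACGTACGTAC", "TTTTGGGGCCCC",
#'                reverse_complement("GGTTGGTTGG"), "AAAA")
#' simulate_pcr(tmpl, p)$sequence
#' @export
simulate_pcr <- function(sequence, primers, try_reverse_strand = TRUE) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- validate_iupac(sequence, "template")

  hit <- pcr_one_strand(template, primers)
  if (!is.null(hit)) {
    hit$strand <- "+"
    return(hit)
  }
  if (try_reverse_strand) {
    hit <- pcr_one_strand(reverse_complement(template), primers)
    if (!is.null(hit)) {
      hit$strand <- "-"
      return(hit)
    }
  }
  NULL
}

# one orientation of the simulate_pcr scan; returns amplicon sans strand
pcr_one_strand <- function(template, primers) {
  fwd_len <- nchar(primers$forward)
  rev_len <- nchar(primers$reverse)
  n <- nchar(template)
  if (n < 1L) return(NULL)

  fwd <- align_primer(primers$forward, template)
  if (fwd$score < primers$threshold * fwd_len) return(NULL)
  if (!anchor_ok(fwd, "last")) return(NULL)

  # reverse primer binds the minus strand; align its reverse complement on
  # the plus strand, strictly downstream of the forward hit
  if (fwd$end >= n) return(NULL)
  region <- substr(template, fwd$end + 1L, n)
  rev <- align_primer(reverse_complement(primers$reverse), region)
  if (rev$score < primers$threshold * rev_len) return(NULL)
  # the reverse primer's 3' end faces the insert: the first three
  # template-orientation columns of its complemented alignment
  if (!anchor_ok(rev, "first")) return(NULL)
  rev$start <- rev$start + fwd$end
  rev$end <- rev$end + fwd$end

  if (primers$keep_primers) {
    start <- fwd$start
    end <- rev$end
  } else {
    start <- fwd$end
    end <- rev$start
    if (end <= start) return(NULL)  # abutting/overlapping primers, no insert
  }
  structure(list(sequence = substr(template, start + 1L, end),
                 start = start, end = end,
                 includes_primers = primers$keep_primers,
                 fwd_hit = fwd, rev_hit = rev),
            class = "amplicon")
}
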