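# Synthetic source-FASTA generator with planted, ground-truth-known
# structure: primer sites (degenerate positions resolved per record), shared
# inserts between chosen species pairs, planted primer mismatches, off-genus
# records and genus-level ("sp.") records. Every downstream stage can be
# tested offline against the manifest this module emits.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# resolve every IUPAC ambiguity code to one concrete base, uniformly at
# random, so ambiguity matching is exercised by the fixtures
resolve_degenerate <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    ex <- iupac_expand(ch)
    if (length(ex) == 1L) ex else sample(ex, 1L)
  }, character(1L)), collapse = "")
}

count_matches <- function(pattern, x) {
  m <- gregexpr(pattern, x)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) 0L else length(m)
}

#' Specify a synthetic fixture
#'
#' @param genus genus of the planted records.
#' @param n_species number of in-genus species.
#' @param n_records_per_species records per species (all records of one
#'   species carry the same insert, exercising redundant-amplicon collapse).
#' @param n_shared_amplicons number of species pairs sharing an identical
#'   insert; pairs may overlap, in which case the shared-insert relation is
#'   transitive and the expected SA groups are the connected components of
#'   the pair graph. Must not exceed `choose(n_species, 2)`.
#' @param insert_length length of the planted insert between primer sites.
#' @param flank_length length of the random flanks on each side.
#' @param mismatch_plan `NULL` or a data.frame with columns `record` (1-based
#'   index into the main in-genus records), `primer` (`"fwd"`/`"rev"`),
#'   `pos3` (position from the primer's 3' end, 1-based) and `base` (the
#'   template base to plant there; it must fall outside the primer code's
#'   expansion set, otherwise the plan is contradictory).
#' @param offgenus_fraction fraction (of main records) of extra records from
#'   a different genus, with valid primer sites — exercising the genus filter.
#' @param unwanted_taxa_fraction fraction of extra `"<genus> sp."` records,
#'   each with its own unique insert — exercising the taxonomy filter.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(genus = "Fusarium", n_species = 6L,
                         n_records_per_species = 2L,
                         n_shared_amplicons = 1L, insert_length = 60L,
                         flank_length = 25L, mismatch_plan = NULL,
                         offgenus_fraction = 0.1,
                         unwanted_taxa_fraction = 0.1, seed = 1L) {
  stopifnot(n_species >= 1L, n_records_per_species >= 1L,
            n_shared_amplicons >= 0L,
            n_shared_amplicons <= choose(n_species, 2L),
            insert_length >= 10L, flank_length >= 0L,
            offgenus_fraction >= 0, unwanted_taxa_fraction >= 0)
  if (!is.null(mismatch_plan)) {
    stopifnot(is.data.frame(mismatch_plan),
              all(c("record", "primer", "pos3", "base") %in%
                    names(mismatch_plan)),
              all(mismatch_plan$primer %in% c("fwd", "rev")),
              all(mismatch_plan$pos3 >= 1L),
              all(toupper(mismatch_plan$base) %in% c("A", "C", "G", "T")))
  }
  structure(list(genus = genus, n_species = as.integer(n_species),
                 n_records_per_species = as.integer(n_records_per_species),
                 n_shared_amplicons = as.integer(n_shared_amplicons),
                 insert_length = as.integer(insert_length),
                 flank_length = as.integer(flank_length),
                 mismatch_plan = mismatch_plan,
                 offgenus_fraction = offgenus_fraction,
                 unwanted_taxa_fraction = unwanted_taxa_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic source FASTA with known ground truth
#'
#' Each record is assembled as
#' `flank + forward-site + insert + revcomp(reverse)-site + flank`, with
#' degenerate primer positions resolved to a concrete base per record and
#' mismatches injected per plan. Random segments are screened (and
#' regenerated on collision) so they contain no spurious full-score primer
#' site on either strand. The manifest records, per record, the expected
#' amplicon and the expected taxon after filtering and SA grouping, and the
#' returned truth object carries the expected database summary.
#'
#' @param spec a [fixture_spec()].
#' @param primers a [primer_pair()]; expected amplifiability is computed
#'   under this pair's threshold and `keep_primers` setting.
#' @param fasta_path output FASTA (generic-dialect headers).
#' @param manifest_path output manifest TSV; default `<fasta_path>.manifest.tsv`.
#' @return invisibly, a list: `fasta`, `manifest`, `records` (per-record
#'   table), `expected_summary` (as [db_summary()]), `expected_sa_members`
#'   (named list of member vectors), `n_sp_entries_removed`,
#'   `n_offgenus`, `n_unwanted`.
#' @export
generate_fixture <- function(spec, primers,
                             fasta_path,
                             manifest_path = paste0(fasta_path,
                                                    ".manifest.tsv")) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(primers, "primer_pair"))
  fwd <- primers$forward
  rev <- primers$reverse
  rc_rev <- reverse_complement(rev)
  L_f <- nchar(fwd)
  L_r <- nchar(rev)

  plan <- spec$mismatch_plan
  if (!is.null(plan)) {
    too_long <- (plan$primer == "fwd" & plan$pos3 > L_f) |
      (plan$primer == "rev" & plan$pos3 > L_r)
    if (any(too_long)) {
      stop("contradictory mismatch plan: position from 3' end beyond ",
           "primer length", call. = FALSE)
    }
    for (k in seq_len(nrow(plan))) {
      code <- if (plan$primer[k] == "fwd") {
        substr(fwd, L_f - plan$pos3[k] + 1L, L_f - plan$pos3[k] + 1L)
      } else {
        substr(rc_rev, plan$pos3[k], plan$pos3[k])
      }
      if (toupper(plan$base[k]) %in% iupac_expand(code)) {
        stop("contradictory mismatch plan: replacement base '",
             plan$base[k], "' is inside the expansion of primer code '",
             code, "' and would not be a mismatch", call. = FALSE)
      }
    }
  }

  with_seed(spec$seed, {
    n_sp <- spec$n_species
    species <- paste(spec$genus, sprintf("simspecies%02d", seq_len(n_sp)))

    # choose shared pairs; expected SA groups are connected components
    chosen <- if (spec$n_shared_amplicons > 0L) {
      all_pairs <- utils::combn(n_sp, 2L)
      all_pairs[, sample(ncol(all_pairs), spec$n_shared_amplicons),
                drop = FALSE]
    } else {
      matrix(integer(), nrow = 2L)
    }
    parent <- seq_len(n_sp)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (k in seq_len(ncol(chosen))) {
      a <- find(chosen[1L, k]); b <- find(chosen[2L, k])
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_len(n_sp), find, integer(1L))

    # patterns whose full-score occurrence anywhere unplanned must be avoided
    site_patterns <- unique(c(iupac_regex(fwd), iupac_regex(rc_rev),
                              iupac_regex(reverse_complement(fwd)),
                              iupac_regex(rev)))
    clean_segment <- function(n) {
      for (try in 1:100) {
        s <- random_dna(n)
        if (all(vapply(site_patterns, count_matches, integer(1L),
                       x = s) == 0L)) {
          return(s)
        }
      }
      stop("could not draw a segment free of primer sites; ",
           "primers too permissive for these fixture dimensions",
           call. = FALSE)
    }

    # one insert per component, plus one per unwanted/off-genus record
    n_main <- n_sp * spec$n_records_per_species
    n_unwanted <- round(spec$unwanted_taxa_fraction * n_main)
    n_off <- round(spec$offgenus_fraction * n_main)
    comps <- unique(comp)
    n_inserts <- length(comps) + n_unwanted + n_off
    inserts <- character(0L)
    while (length(inserts) < n_inserts) {
      cand <- clean_segment(spec$insert_length)
      if (!cand %in% inserts) inserts <- c(inserts, cand)
    }
    comp_insert <- stats::setNames(inserts[seq_along(comps)],
                                   as.character(comps))

    # record plan: main (species-major), then unwanted, then off-genus
    rec_species <- c(rep(species, each = spec$n_records_per_species),
                     rep(paste(spec$genus, "sp."), n_unwanted),
                     sprintf("Othergenus alienus%02d", seq_len(n_off)))
    rec_insert <- c(rep(comp_insert[as.character(comp)],
                        each = spec$n_records_per_species),
                    inserts[length(comps) + seq_len(n_unwanted)],
                    inserts[length(comps) + n_unwanted + seq_len(n_off)])
    n_rec <- length(rec_species)
    rec_id <- sprintf("rec%04d", seq_len(n_rec))

    templates <- character(n_rec)
    exp_amplicon <- character(n_rec)
    for (i in seq_len(n_rec)) {
      site_f <- resolve_degenerate(fwd)
      site_r <- resolve_degenerate(rc_rev)

      k_int_f <- 0L; k_int_r <- 0L; anchor_broken <- FALSE
      if (!is.null(plan) && i <= n_main) {
        rows <- plan[plan$record == i, , drop = FALSE]
        for (k in seq_len(nrow(rows))) {
          b <- toupper(rows$base[k])
          if (rows$primer[k] == "fwd") {
            pos <- L_f - rows$pos3[k] + 1L
            substr(site_f, pos, pos) <- b
            if (rows$pos3[k] <= 3L) anchor_broken <- TRUE
            else k_int_f <- k_int_f + 1L
          } else {
            substr(site_r, rows$pos3[k], rows$pos3[k]) <- b
            if (rows$pos3[k] <= 3L) anchor_broken <- TRUE
            else k_int_r <- k_int_r + 1L
          }
        }
      }

      n_mut <- k_int_f + k_int_r + anchor_broken
      for (try in 1:100) {
        tmpl <- paste0(clean_segment(spec$flank_length), site_f,
                       rec_insert[i], site_r,
                       clean_segment(spec$flank_length))
        n_f <- count_matches(iupac_regex(fwd), tmpl)
        n_r <- count_matches(iupac_regex(rc_rev), tmpl)
        n_minus <- count_matches(iupac_regex(reverse_complement(fwd)),
                                 tmpl) +
          count_matches(iupac_regex(rev), tmpl)
        ok <- if (n_mut == 0L) {
          n_f == 1L && n_r == 1L && n_minus == 0L
        } else {
          n_f <= 1L && n_r <= 1L && n_minus == 0L
        }
        if (ok) break
        if (try == 100L) stop("could not assemble a clean template",
                              call. = FALSE)
      }
      templates[i] <- tmpl

      amplifiable <- !anchor_broken &&
        (L_f - k_int_f) + 1e-9 >= primers$threshold * L_f &&
        (L_r - k_int_r) + 1e-9 >= primers$threshold * L_r
      exp_amplicon[i] <- if (!amplifiable) {
        "-"
      } else if (primers$keep_primers) {
        paste0(site_f, rec_insert[i], site_r)
      } else {
        rec_insert[i]
      }
    }

    # ground truth database, computed from the plan alone (independent of
    # the pipeline implementation): entries = distinct expected amplicons of
    # amplifiable in-genus records; "<genus> sp."-only entries are filtered
    in_genus <- rec_species != paste(spec$genus, "sp.") &
      !startsWith(rec_species, "Othergenus ")
    is_sp <- rec_species == paste(spec$genus, "sp.")
    usable <- exp_amplicon != "-" & (in_genus | is_sp)
    entry_taxa <- lapply(split(rec_species[usable], exp_amplicon[usable]),
                         unique)
    # taxonomy filter: drop "sp." labels, then empty entries
    sp_label <- paste(spec$genus, "sp.")
    entry_taxa <- lapply(entry_taxa, function(t) setdiff(t, sp_label))
    n_sp_removed <- sum(vapply(entry_taxa, length, integer(1L)) == 0L)
    entry_taxa <- entry_taxa[vapply(entry_taxa, length, integer(1L)) > 0L]

    entry_seqs <- sort(names(entry_taxa), method = "radix")
    n_taxa <- vapply(entry_taxa[entry_seqs], length, integer(1L))
    exp_name <- character(length(entry_seqs))
    exp_name[n_taxa == 1L] <- vapply(
      entry_taxa[entry_seqs][n_taxa == 1L],
      function(t) gsub("\\s+", "_", t[[1L]]), character(1L))
    exp_name[n_taxa >= 2L] <- paste0(spec$genus, "_SA",
                                     seq_len(sum(n_taxa >= 2L)))
    names(exp_name) <- entry_seqs
    sa_members <- lapply(entry_taxa[entry_seqs][n_taxa >= 2L], sort)
    names(sa_members) <- exp_name[n_taxa >= 2L]

    single_labels <- unlist(entry_taxa[entry_seqs][n_taxa == 1L],
                            use.names = FALSE)
    expected_summary <- list(
      total_variants = length(entry_seqs),
      sa_variants = sum(n_taxa >= 2L),
      complex_variants = sum(grepl("\\bcomplex$", single_labels)),
      unique_species_taxa = length(unique(single_labels)),
      sa_taxa = sum(n_taxa >= 2L),
      attributions = length(unique(single_labels)) + sum(n_taxa >= 2L)
    )

    exp_group <- vapply(seq_len(n_rec), function(i) {
      if (exp_amplicon[i] == "-" || !in_genus[i]) return("-")
      nm <- exp_name[exp_amplicon[i]]
      if (is.na(nm)) "-" else nm
    }, character(1L))

    # write FASTA (generic dialect) and manifest
    fasta_lines <- character(2L * n_rec)
    fasta_lines[seq(1L, by = 2L, length.out = n_rec)] <-
      paste0(">", rec_id, " ", rec_species)
    fasta_lines[seq(2L, by = 2L, length.out = n_rec)] <- templates
    writeLines(fasta_lines, fasta_path)

    records <- data.frame(record_id = rec_id, species = rec_species,
                          expected_amplicon = exp_amplicon,
                          expected_group = exp_group,
                          stringsAsFactors = FALSE)
    utils::write.table(records, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)

    invisible(list(fasta = fasta_path, manifest = manifest_path,
                   records = records,
                   expected_summary = expected_summary,
                   expected_sa_members = sa_members,
                   n_sp_entries_removed = n_sp_removed,
                   n_offgenus = n_off, n_unwanted = n_unwanted))
  })
}
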