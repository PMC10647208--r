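# Core database construction: amplification over all source records,
# collapsing identical amplicons, taxonomy filtering, Shared-Amplicon (SA)
# grouping, merging and summaries.

#' Construct an ASV database object
#'
#' Low-level constructor used by [build_database()], [read_db()] and tests.
#' An `asv_db` is a genus-scoped collection of unique amplicon sequences,
#' each mapped to the set of species-level taxa observed to carry it.
#'
#' @param genus genus name the database is scoped to.
#' @param sequences character vector of unique amplicon sequences.
#' @param taxa list of character vectors (species labels per sequence).
#' @param accessions list of character vectors (source accessions per
#'   sequence); defaults to empty sets.
#' @param lineage character vector of lineage ranks down to the genus, used
#'   when composing taxon strings on export.
#' @param provenance list of provenance records.
#' @param filter_log named list of filter counters.
#' @return an object of class `asv_db`; `assigned_name` is `NA` until
#'   [make_sa_groups()] runs.
#' @export
asv_db <- function(genus, sequences = character(), taxa = list(),
                   accessions = NULL, lineage = character(),
                   provenance = list(), filter_log = list()) {
  stopifnot(is.character(genus), length(genus) == 1L, nzchar(trimws(genus)))
  sequences <- toupper(sequences)
  if (anyDuplicated(sequences)) {
    stop("entry sequences must be unique", call. = FALSE)
  }
  stopifnot(length(taxa) == length(sequences))
  if (is.null(accessions)) {
    accessions <- replicate(length(sequences), character(), simplify = FALSE)
  }
  stopifnot(length(accessions) == length(sequences))
  entries <- data.frame(sequence = sequences,
                        assigned_name = rep(NA_character_, length(sequences)),
                        stringsAsFactors = FALSE)
  entries$taxa <- unname(lapply(taxa, function(t) sort(unique(t))))
  entries$accessions <- unname(lapply(accessions,
                                      function(a) sort(unique(a))))
  structure(list(genus = trimws(genus), lineage = lineage, entries = entries,
                 sa_groups = empty_sa_groups(), provenance = provenance,
                 filter_log = filter_log),
            class = "asv_db")
}

empty_sa_groups <- function() {
  g <- data.frame(n = integer(), sequence = character(),
                  stringsAsFactors = FALSE)
  g$members <- list()
  g
}

same_genus <- function(a, b) {
  tolower(trimws(a)) == tolower(trimws(b))
}

filter_log_message <- function(db) {
  fl <- db$filter_log
  if (length(fl) == 0L) return("no filter log available")
  flat <- unlist(fl)
  paste("filter log:",
        paste(names(flat), flat, sep = "=", collapse = ", "))
}

# majority lineage prefix (ranks down to genus) across parsed records;
# a trailing binomial species rank is dropped
consensus_lineage <- function(records) {
  lins <- records$lineage[!is.na(records$lineage)]
  if (length(lins) == 0L) return(character())
  prefixes <- vapply(lins, function(l) {
    ranks <- strsplit(l, ";", fixed = TRUE)[[1L]]
    if (length(ranks) > 0L && grepl("\\s", ranks[length(ranks)])) {
      ranks <- ranks[-length(ranks)]
    }
    paste(ranks, collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  top <- names(sort(table(prefixes), decreasing = TRUE))[1L]
  if (!nzchar(top)) character() else strsplit(top, ";", fixed = TRUE)[[1L]]
}

#' Build a genus-specific ASV database from source records
#'
#' Keeps only records whose genus matches the target (case-insensitive,
#' whitespace-trimmed), simulates PCR amplification on each with
#' [simulate_pcr()], and collapses identical amplicons into one entry per
#' distinct sequence, accumulating the species labels and accessions that
#' carry it. Redundant amplicons — identical sequence, identical taxonomy —
#' thereby collapse to a single entry. Records yielding no amplicon are
#' counted in the filter log. A record of the right genus whose header gave
#' no species epithet is labelled `"<Genus> sp."` so the default taxonomy
#' filter can remove it later.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param genus target genus.
#' @param primers a [primer_pair()].
#' @param try_reverse_strand passed to [simulate_pcr()].
#' @return an `asv_db` (not yet SA-grouped; see [make_sa_groups()]). Zero
#'   amplifiable records yield an empty database with a prominent message,
#'   not an error.
#' @export
build_database <- function(records, genus, primers,
                           try_reverse_strand = TRUE) {
  stopifnot(is.data.frame(records), inherits(primers, "primer_pair"),
            is.character(genus), length(genus) == 1L, nzchar(trimws(genus)))
  genus <- trimws(genus)

  in_genus <- !is.na(records$genus) &
    vapply(records$genus, same_genus, logical(1L), b = genus)
  kept <- records[in_genus, , drop = FALSE]
  n_wrong_genus <- nrow(records) - nrow(kept)

  species <- kept$species
  species[is.na(species)] <- paste(genus, "sp.")

  seqs <- character(nrow(kept))
  ok <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    amp <- simulate_pcr(kept$sequence[i], primers,
                        try_reverse_strand = try_reverse_strand)
    if (!is.null(amp)) {
      seqs[i] <- amp$sequence
      ok[i] <- TRUE
    }
  }
  n_no_amplicon <- sum(!ok)

  filter_log <- list(build = list(
    n_input = nrow(records),
    n_wrong_genus = n_wrong_genus,
    n_no_amplicon = n_no_amplicon,
    n_amplified = sum(ok)
  ))
  provenance <- list(list(
    action = "build", genus = genus,
    forward = primers$forward, reverse = primers$reverse,
    threshold = primers$threshold, keep_primers = primers$keep_primers,
    n_input_records = nrow(records)
  ))

  if (!any(ok)) {
    message("build_database: no amplifiable records for genus '", genus,
            "' (", n_wrong_genus, " wrong genus, ", n_no_amplicon,
            " records with no primer match at threshold ",
            primers$threshold, ")")
    return(asv_db(genus, lineage = consensus_lineage(records),
                  provenance = provenance, filter_log = filter_log))
  }

  amp_seq <- seqs[ok]
  amp_species <- species[ok]
  amp_acc <- kept$accession[ok]
  uniq <- sort(unique(amp_seq), method = "radix")
  idx <- split(seq_along(amp_seq), factor(amp_seq, levels = uniq))
  asv_db(genus,
         sequences = uniq,
         taxa = lapply(idx, function(i) amp_species[i]),
         accessions = lapply(idx, function(i) amp_acc[i]),
         lineage = consensus_lineage(kept),
         provenance = provenance,
         filter_log = filter_log)
}

#' Default unwanted-taxonomy patterns
#'
#' Regular expressions over species labels matching records identified only
#' to genus level or with uncertain affinity: epithet exactly `"sp."`,
#' epithet beginning `"aff."`, epithet beginning `"cf."`.
#'
#' @return character vector of regular expressions.
#' @export
default_exclude_patterns <- function() {
  c("^\\S+ sp\\.$", "^\\S+ aff\\.", "^\\S+ cf\\.")
}

#' Filter unwanted taxa out of a database
#'
#' Removes matching species labels from every entry's taxa set; entries whose
#' taxa set becomes empty are deleted. The filter log records per-pattern
#' removal counts. With an empty pattern list the database is returned
#' unchanged.
#'
#' @param db an `asv_db`.
#' @param exclude_patterns regular expressions over species labels; default
#'   [default_exclude_patterns()].
#' @return the filtered `asv_db`.
#' @export
filter_taxa <- function(db, exclude_patterns = default_exclude_patterns()) {
  stopifnot(inherits(db, "asv_db"), is.character(exclude_patterns))
  if (length(exclude_patterns) == 0L) return(db)

  removed <- stats::setNames(integer(length(exclude_patterns)),
                             exclude_patterns)
  new_taxa <- lapply(db$entries$taxa, function(taxa) {
    for (p in exclude_patterns) {
      hit <- grepl(p, taxa)
      if (any(hit)) {
        removed[p] <<- removed[p] + sum(hit)
        taxa <- taxa[!hit]
      }
    }
    taxa
  })
  keep <- vapply(new_taxa, length, integer(1L)) > 0L
  entries <- db$entries[keep, , drop = FALSE]
  entries$taxa <- new_taxa[keep]
  rownames(entries) <- NULL
  db$entries <- entries
  # names assigned before filtering are stale; grouping must be re-run
  db$entries$assigned_name <- rep(NA_character_, nrow(entries))
  db$sa_groups <- empty_sa_groups()
  db$filter_log$taxa_filter <- list(
    removed_taxa = as.list(removed),
    entries_removed = sum(!keep)
  )
  db$provenance <- c(db$provenance, list(list(
    action = "filter_taxa", patterns = exclude_patterns)))
  db
}

#' Assign taxon names and build Shared-Amplicon groups
#'
#' Entries carried by a single species get the name
#' `GenusName_SpeciesName` (whitespace replaced by underscores; a
#' species-complex label keeps its `complex` marker, e.g.
#' `Fusarium_tricinctum_complex`). Entries carried by two or more species
#' become Shared Amplicons named `GenusName_SAn`, with `n` assigned
#' sequentially from 1 in lexicographic order of the amplicon sequence —
#' deterministic and independent of input order. The SA group list is rebuilt
#' from scratch, and entries are reordered canonically by sequence.
#'
#' @param db an `asv_db`.
#' @return the finalized `asv_db`.
#' @export
make_sa_groups <- function(db) {
  stopifnot(inherits(db, "asv_db"))
  ord <- order(db$entries$sequence, method = "radix")
  entries <- db$entries[ord, , drop = FALSE]
  rownames(entries) <- NULL

  n_taxa <- vapply(entries$taxa, length, integer(1L))
  is_sa <- n_taxa >= 2L
  names_out <- character(nrow(entries))
  names_out[!is_sa] <- vapply(entries$taxa[!is_sa], function(t) {
    gsub("\\s+", "_", t[[1L]])
  }, character(1L))
  names_out[is_sa] <- paste0(db$genus, "_SA", seq_len(sum(is_sa)))
  entries$assigned_name <- names_out

  sa <- entries[is_sa, , drop = FALSE]
  groups <- data.frame(n = seq_len(nrow(sa)), sequence = sa$sequence,
                       stringsAsFactors = FALSE)
  groups$members <- sa$taxa
  db$entries <- entries
  db$sa_groups <- groups
  db
}

#' Merge two databases of the same genus
#'
#' Unions entries by amplicon sequence (taxa and accession sets are unioned
#' per sequence), so a sequence known from both sources under different
#' species becomes a new Shared Amplicon, and exact duplicates collapse.
#' SA numbering is reassigned from scratch on the union — numbering is
#' database-scoped, so the merged database is renumbered as a whole.
#' Provenance is concatenated. Merging a database with itself returns a
#' database with identical content (idempotence), and the merge is
#' commutative up to canonical ordering.
#'
#' @param db1,db2 `asv_db` objects with the same genus (case-insensitive);
#'   a genus mismatch is a fatal error.
#' @return the merged, finalized `asv_db`.
#' @export
merge_databases <- function(db1, db2) {
  stopifnot(inherits(db1, "asv_db"), inherits(db2, "asv_db"))
  if (!same_genus(db1$genus, db2$genus)) {
    stop("cannot merge databases with different genera: '", db1$genus,
         "' vs '", db2$genus, "'", call. = FALSE)
  }
  seqs <- c(db1$entries$sequence, db2$entries$sequence)
  taxa <- c(db1$entries$taxa, db2$entries$taxa)
  accs <- c(db1$entries$accessions, db2$entries$accessions)
  uniq <- sort(unique(seqs), method = "radix")
  idx <- split(seq_along(seqs), factor(seqs, levels = uniq))
  merged <- asv_db(
    db1$genus,
    sequences = uniq,
    taxa = lapply(idx, function(i) unlist(taxa[i])),
    accessions = lapply(idx, function(i) unlist(accs[i])),
    lineage = if (length(db1$lineage) > 0L) db1$lineage else db2$lineage,
    provenance = c(db1$provenance, db2$provenance,
                   list(list(action = "merge",
                             n_entries = c(nrow(db1$entries),
                                           nrow(db2$entries))))),
    filter_log = list(merge = list(
      n_db1 = nrow(db1$entries), n_db2 = nrow(db2$entries),
      n_union = length(uniq)))
  )
  make_sa_groups(merged)
}

#' Summarize a finalized database
#'
#' Counts mirror the three-way split used to characterize a reference
#' database: variants resolved to a single species, to a species complex, or
#' to a Shared Amplicon group.
#'
#' @param db an `asv_db` with SA groups computed.
#' @return a list: `total_variants`, `sa_variants`, `complex_variants`
#'   (single-taxon entries whose label ends in "complex"),
#'   `unique_species_taxa` (distinct species-level labels over single-taxon
#'   entries, species complexes included), `sa_taxa` (number of SA groups)
#'   and `attributions` (`unique_species_taxa + sa_taxa`, the total number of
#'   distinct taxonomic answers the database can return).
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "asv_db"))
  n_taxa <- vapply(db$entries$taxa, length, integer(1L))
  single <- n_taxa == 1L
  single_labels <- vapply(db$entries$taxa[single], `[[`, character(1L), 1L)
  complex_var <- grepl("\\bcomplex$", single_labels)
  list(
    total_variants = nrow(db$entries),
    sa_variants = sum(n_taxa >= 2L),
    complex_variants = sum(complex_var),
    unique_species_taxa = length(unique(single_labels)),
    sa_taxa = nrow(db$sa_groups),
    attributions = length(unique(single_labels)) + nrow(db$sa_groups)
  )
}

#' @export
print.asv_db <- function(x, ...) {
  s <- db_summary(x)
  cat("<asv_db> genus ", x$genus, ": ", s$total_variants,
      " variants (", s$sa_variants, " SA, ", s$complex_variants,
      " species complex); ", s$unique_species_taxa,
      " species taxa + ", s$sa_taxa, " SA taxa = ", s$attributions,
      " possible attributions\n", sep = "")
  invisible(x)
}

#' @export
summary.asv_db <- function(object, ...) db_summary(object)

# --- persistence ----------------------------------------------------------

#' Write a database to its JSON document form
#'
#' The single-document on-disk form used between pipeline steps: genus,
#' lineage, entries (canonically ordered by sequence), SA manifest,
#' provenance and filter log.
#'
#' @param db an `asv_db`.
#' @param path output path.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "asv_db"))
  ord <- order(db$entries$sequence, method = "radix")
  entries <- db$entries[ord, , drop = FALSE]
  doc <- list(
    format = "asvrefdb-db",
    version = 1L,
    genus = db$genus,
    lineage = as.list(db$lineage),
    entries = lapply(seq_len(nrow(entries)), function(i) {
      list(sequence = entries$sequence[i],
           taxa = as.list(entries$taxa[[i]]),
           accessions = as.list(entries$accessions[[i]]),
           assigned_name = entries$assigned_name[i])
    }),
    sa_groups = lapply(seq_len(nrow(db$sa_groups)), function(i) {
      list(n = db$sa_groups$n[i],
           sequence = db$sa_groups$sequence[i],
           members = as.list(db$sa_groups$members[[i]]))
    }),
    provenance = db$provenance,
    filter_log = db$filter_log
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a database from its JSON document form
#'
#' @param path a file written by [write_db()].
#' @return an `asv_db`.
#' @export
read_db <- function(path) {
  if (!file.exists(path)) stop("no such database file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "asvrefdb-db")) {
    stop("'", path, "' is not an asvrefdb database document", call. = FALSE)
  }
  seqs <- vapply(doc$entries, `[[`, character(1L), "sequence")
  db <- asv_db(
    genus = doc$genus,
    sequences = seqs,
    taxa = lapply(doc$entries, function(e) unlist(e$taxa)),
    accessions = lapply(doc$entries,
                        function(e) as.character(unlist(e$accessions))),
    lineage = as.character(unlist(doc$lineage)),
    provenance = doc$provenance,
    filter_log = doc$filter_log
  )
  db$entries$assigned_name <- vapply(doc$entries, function(e) {
    if (is.null(e$assigned_name)) NA_character_ else e$assigned_name
  }, character(1L))
  if (length(doc$sa_groups) > 0L) {
    groups <- data.frame(
      n = vapply(doc$sa_groups, function(g) as.integer(g$n), integer(1L)),
      sequence = vapply(doc$sa_groups, `[[`, character(1L), "sequence"),
      stringsAsFactors = FALSE
    )
    groups$members <- lapply(doc$sa_groups, function(g) unlist(g$members))
    db$sa_groups <- groups
  }
  db
}

#' Canonical content form of a database
#'
#' Serializes the scientific content (genus, lineage, entries and SA groups
#' in canonical sequence order) while excluding run metadata (provenance,
#' filter log), so that two databases built along different routes can be
#' compared byte-for-byte.
#'
#' @param db an `asv_db`.
#' @return a character scalar (canonical JSON).
#' @export
db_canonical <- function(db) {
  ord <- order(db$entries$sequence, method = "radix")
  entries <- db$entries[ord, , drop = FALSE]
  doc <- list(
    genus = db$genus,
    lineage = as.list(db$lineage),
    entries = lapply(seq_len(nrow(entries)), function(i) {
      list(sequence = entries$sequence[i],
           taxa = as.list(sort(entries$taxa[[i]])),
           accessions = as.list(sort(entries$accessions[[i]])),
           assigned_name = entries$assigned_name[i])
    }),
    sa_groups = lapply(seq_len(nrow(db$sa_groups)), function(i) {
      list(n = db$sa_groups$n[i],
           sequence = db$sa_groups$sequence[i],
           members = as.list(sort(db$sa_groups$members[[i]])))
    })
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}
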