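# Reading source FASTA files in public-database header dialects and writing
# the finished reference database in a form downstream amplicon pipelines
# consume (feature FASTA + taxonomy TSV).

SOURCE_DBS <- c("generic", "silva", "unite", "ena", "ncbi", "ddbj",
                "rnacentral")

# --- header parsing -------------------------------------------------------

# Truncate a free-text organism name to a species-level label:
# "Genus epithet", "Genus epithet complex", "Genus sp.", "Genus aff. xxx".
# Sub-species annotations (var., f. sp., strain ids) are cut at the epithet.
parse_binomial <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L || !grepl("^[A-Za-z]", toks[1L])) {
    return(list(genus = NA_character_, species = NA_character_))
  }
  genus <- toks[1L]
  if (length(toks) == 1L) {
    return(list(genus = genus, species = NA_character_))
  }
  epithet <- toks[2L]
  if (epithet %in% c("aff.", "cf.") && length(toks) >= 3L) {
    return(list(genus = genus,
                species = paste(genus, epithet, toks[3L])))
  }
  if (epithet == "sp.") {
    return(list(genus = genus, species = paste(genus, "sp.")))
  }
  species <- paste(genus, epithet)
  # species-complex names keep their "complex" marker: one taxon, not many
  if (length(toks) >= 3L && tolower(toks[3L]) == "complex") {
    species <- paste(species, "complex")
  } else if (length(toks) >= 4L && tolower(toks[3L]) == "species" &&
             tolower(toks[4L]) == "complex") {
    species <- paste(species, "complex")
  }
  list(genus = genus, species = species)
}

strip_rank_prefix <- function(x) sub("^[a-zA-Z]__", "", x)

# Table of header grammars, one parser per supported source database.
# Each parser maps a raw header (">" removed) to accession, description,
# lineage ranks (character vector or NULL), genus and species label.
HEADER_DIALECTS <- list(
  generic = function(h) {
    acc <- sub("\\s.*$", "", h)
    desc <- trimws(sub("^\\S+\\s*", "", h))
    c(list(accession = acc, description = desc, lineage = NULL),
      parse_binomial(desc))
  },
  silva = function(h) {
    # ">X80725.1.1497 Bacteria;Proteobacteria;...;Escherichia coli"
    acc <- sub("\\s.*$", "", h)
    taxpath <- trimws(sub("^\\S+\\s*", "", h))
    ranks <- trimws(strsplit(taxpath, ";", fixed = TRUE)[[1L]])
    species <- if (length(ranks) > 0L) ranks[length(ranks)] else ""
    bn <- parse_binomial(species)
    list(accession = acc, description = taxpath, lineage = ranks,
         genus = bn$genus, species = bn$species)
  },
  unite = function(h) {
    # ">Name|ACC|SH1234.08FU|reps|k__Fungi;p__...;s__Genus_species"
    fields <- strsplit(h, "|", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      return(HEADER_DIALECTS$generic(h))
    }
    acc <- fields[2L]
    taxfield <- fields[length(fields)]
    ranks <- strip_rank_prefix(trimws(strsplit(taxfield, ";",
                                               fixed = TRUE)[[1L]]))
    ranks <- gsub("_", " ", ranks)
    species <- if (length(ranks) > 0L) ranks[length(ranks)] else ""
    bn <- parse_binomial(species)
    genus <- bn$genus
    gq <- grep("^g__", trimws(strsplit(taxfield, ";", fixed = TRUE)[[1L]]),
               value = TRUE)
    if (length(gq) == 1L && nzchar(strip_rank_prefix(gq))) {
      genus <- strip_rank_prefix(gq)
    }
    list(accession = acc, description = h, lineage = ranks,
         genus = genus, species = bn$species)
  },
  ena = function(h) {
    # ">ACC.1 Fusarium oxysporum strain Foo elongation factor 1-alpha"
    acc <- sub("\\s.*$", "", h)
    desc <- trimws(sub("^\\S+\\s*", "", h))
    c(list(accession = acc, description = desc, lineage = NULL),
      parse_binomial(desc))
  },
  rnacentral = function(h) {
    # ">URS00019D9371_9606 Homo sapiens (human) ..." — id token then organism
    acc <- sub("\\s.*$", "", h)
    desc <- trimws(sub("^\\S+\\s*", "", h))
    c(list(accession = acc, description = desc, lineage = NULL),
      parse_binomial(desc))
  }
)
HEADER_DIALECTS$ncbi <- HEADER_DIALECTS$ena
HEADER_DIALECTS$ddbj <- HEADER_DIALECTS$ena

# empty records table with the column contract used across the package
empty_records <- function() {
  data.frame(accession = character(), description = character(),
             sequence = character(), source_db = character(),
             lineage = character(), genus = character(),
             species = character(), verified = character(),
             stringsAsFactors = FALSE)
}

#' Read a source FASTA file
#'
#' Reads a FASTA file downloaded from one of the supported public sequence
#' databases and parses taxonomy out of the headers according to that
#' database's header dialect. Sequences are uppercased and U is normalized to
#' T on ingest (RNAcentral serves RNA alphabets). Records whose sequence
#' contains characters outside the IUPAC nucleotide alphabet are dropped and
#' counted; records whose header yields no genus are kept with an absent
#' lineage (they are removed later by the genus filter, keeping parsing
#' side-effect-free). Duplicate accessions within one file resolve last-wins
#' with a warning.
#'
#' @param path FASTA file.
#' @param dialect one of `"generic"`, `"silva"`, `"unite"`, `"ena"`,
#'   `"ncbi"`, `"ddbj"`, `"rnacentral"`.
#' @return a data.frame with columns `accession`, `description`, `sequence`,
#'   `source_db`, `lineage` (semicolon-joined ranks or `NA`), `genus`,
#'   `species` (species-level label or `NA`) and `verified`; the number of
#'   records dropped for alphabet violations is attached as
#'   `attr(, "n_dropped_alphabet")`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">A1 Fusarium oxysporum", "ACGT",
#'              ">A2 Fusarium solani", "GGTT"), f)
#' read_fasta(f, "generic")
#' @export
read_fasta <- function(path, dialect = "generic") {
  dialect <- match.arg(dialect, SOURCE_DBS)
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path, call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("failed to parse '", path, "' as FASTA: ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) {
    stop("no FASTA records in '", path, "' (dialect tried: ", dialect, ")",
         call. = FALSE)
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)

  ok_alpha <- !grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"),
                     seqs) & nzchar(seqs)
  n_dropped <- sum(!ok_alpha)
  headers <- headers[ok_alpha]
  seqs <- seqs[ok_alpha]
  if (length(seqs) == 0L) {
    stop("no records with a valid nucleotide alphabet in '", path,
         "' (dialect tried: ", dialect, ")", call. = FALSE)
  }

  parser <- HEADER_DIALECTS[[dialect]]
  parsed <- lapply(headers, parser)
  rec <- data.frame(
    accession = vapply(parsed, `[[`, character(1L), "accession"),
    description = vapply(parsed, `[[`, character(1L), "description"),
    sequence = seqs,
    source_db = dialect,
    lineage = vapply(parsed, function(p) {
      if (is.null(p$lineage)) NA_character_
      else paste(p$lineage, collapse = ";")
    }, character(1L)),
    genus = vapply(parsed, function(p) p$genus %||% NA_character_,
                   character(1L)),
    species = vapply(parsed, function(p) p$species %||% NA_character_,
                     character(1L)),
    verified = "unverified",
    stringsAsFactors = FALSE
  )

  dup <- duplicated(rec$accession, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate accession(s) in '", path,
            "'; keeping the last occurrence of each", call. = FALSE)
    rec <- rec[!dup, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "n_dropped_alphabet") <- n_dropped
  rec
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Feature identifier of a reference sequence
#'
#' Lowercase hexadecimal MD5 of the uppercase sequence — the dominant
#' ASV-identifier convention of downstream amplicon pipelines, deterministic
#' across runs and injective over distinct sequences at any realistic scale.
#'
#' @param sequence nucleotide string(s).
#' @return character vector of 32-character hex digests.
#' @export
feature_id <- function(sequence) {
  vapply(toupper(sequence),
         function(s) digest::digest(s, algo = "md5", serialize = FALSE),
         character(1L), USE.NAMES = FALSE)
}

# taxon string for one entry: optional rank-prefixed lineage down to genus,
# then the species-level assigned name
taxon_string <- function(lineage_ranks, assigned_name, rank_prefixes = TRUE) {
  parts <- gsub("\\s+", "_", lineage_ranks)
  if (rank_prefixes) {
    prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
    if (length(parts) > 0L && length(parts) <= 6L) {
      parts <- paste0(utils::tail(prefixes, length(parts)), parts)
    }
    paste(c(parts, paste0("s__", assigned_name)), collapse = ";")
  } else {
    paste(c(parts, assigned_name), collapse = ";")
  }
}

#' Export a finalized database as reference FASTA + taxonomy TSV
#'
#' Writes the reference pair consumed by exact-match secondary taxonomic
#' assignment (100% identity, 100% coverage): a FASTA of unique amplicon
#' sequences whose IDs are MD5 feature identifiers, and a two-column TSV
#' mapping each feature ID to its full taxon string, whose last field is
#' either `GenusName_SpeciesName` or `GenusName_SAn`. Entries are sorted
#' lexicographically by feature ID so output is byte-stable across runs. SA
#' group membership is additionally emitted to a sidecar manifest TSV.
#'
#' @param db a finalized `asv_db` (shared-amplicon groups computed, see
#'   [make_sa_groups()]).
#' @param seqs_path output FASTA path.
#' @param tax_path output taxonomy TSV path.
#' @param sa_manifest_path optional sidecar TSV (`group_id`, `n_species`,
#'   semicolon-joined `species`); defaults to `<tax_path>.sa.tsv`.
#' @param tsv_header write a `Feature ID`/`Taxon` header row (default off).
#' @param rank_prefixes prefix lineage fields with `k__`/`p__`/…/`s__`
#'   (default on, for compatibility with pre-trained-classifier workflows).
#' @return invisibly, a list of summary counts.
#' @export
write_reference <- function(db, seqs_path, tax_path,
                            sa_manifest_path = paste0(tax_path, ".sa.tsv"),
                            tsv_header = FALSE, rank_prefixes = TRUE) {
  stopifnot(inherits(db, "asv_db"))
  if (nrow(db$entries) == 0L) {
    stop("reference database for genus '", db$genus, "' is empty; ",
         filter_log_message(db), call. = FALSE)
  }
  if (anyNA(db$entries$assigned_name)) {
    stop("database not finalized: run make_sa_groups() before exporting",
         call. = FALSE)
  }

  ids <- feature_id(db$entries$sequence)
  ord <- order(ids, method = "radix")
  ids <- ids[ord]
  seqs <- db$entries$sequence[ord]
  names_ord <- db$entries$assigned_name[ord]

  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = seqs_path, width = 80L)

  taxa <- vapply(names_ord, function(nm) {
    taxon_string(db$lineage, nm, rank_prefixes = rank_prefixes)
  }, character(1L), USE.NAMES = FALSE)
  tax_df <- data.frame(`Feature ID` = ids, Taxon = taxa,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tax_df, tax_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = tsv_header)

  if (!is.null(sa_manifest_path)) {
    sa <- db$sa_groups
    sa_df <- data.frame(
      group_id = sprintf("%s_SA%d", db$genus, sa$n),
      n_species = vapply(sa$members, length, integer(1L)),
      species = vapply(sa$members,
                       function(m) paste(sort(m), collapse = ";"),
                       character(1L)),
      stringsAsFactors = FALSE
    )
    utils::write.table(sa_df, sa_manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }

  invisible(list(
    n_sequences = length(ids),
    n_species_level = sum(!grepl("_SA[0-9]+$", names_ord)),
    n_sa = nrow(db$sa_groups)
  ))
}
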