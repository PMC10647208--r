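# Lineage verification: resolve an accession's taxonomy through the ENA
# browser API first, falling back to NCBI Entrez, behind a mandatory
# file-backed cache so a build never requires the network twice for the same
# accession — and never requires it at all in offline mode.

#' Create or load a lineage cache
#'
#' The cache is a TSV file (`accession`, `lineage` semicolon-joined,
#' `genus`, `species`, `source`, `timestamp`) that is append-only across
#' runs: lookups never mutate existing verified entries, and re-running a
#' build issues zero network calls for cached accessions.
#'
#' @param path cache file; created on first write. `NULL` keeps the cache in
#'   memory only.
#' @return a `lineage_cache` object.
#' @export
lineage_cache <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    for (i in seq_len(nrow(tab))) {
      assign(tab$accession[i],
             list(lineage = if (is.na(tab$lineage[i])) character()
                            else strsplit(tab$lineage[i], ";",
                                          fixed = TRUE)[[1L]],
                  genus = tab$genus[i], species = tab$species[i],
                  source = tab$source[i], timestamp = tab$timestamp[i]),
             envir = env)
    }
  }
  structure(list(env = env, path = path), class = "lineage_cache")
}

cache_get <- function(cache, accession) {
  if (exists(accession, envir = cache$env, inherits = FALSE)) {
    get(accession, envir = cache$env, inherits = FALSE)
  } else {
    NULL
  }
}

cache_put <- function(cache, accession, value) {
  if (!is.null(cache_get(cache, accession))) return(invisible(cache))
  value$timestamp <- value$timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  assign(accession, value, envir = cache$env)
  if (!is.null(cache$path)) {
    row <- data.frame(accession = accession,
                      lineage = paste(value$lineage, collapse = ";"),
                      genus = value$genus %||% NA_character_,
                      species = value$species %||% NA_character_,
                      source = value$source,
                      timestamp = value$timestamp,
                      stringsAsFactors = FALSE)
    new_file <- !file.exists(cache$path)
    suppressWarnings(
      utils::write.table(row, cache$path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = new_file,
                         append = !new_file)
    )
  }
  invisible(cache)
}

#' @export
print.lineage_cache <- function(x, ...) {
  cat("<lineage_cache> ", length(ls(x$env)), " accession(s)",
      if (!is.null(x$path)) paste0(" backed by ", x$path) else " (in-memory)",
      "\n", sep = "")
  invisible(x)
}

# --- response parsers (pure, tested against committed mock responses) ------

#' Parse an ENA EMBL flat-file response into a lineage
#'
#' Extracts the organism (`OS` line) and classification (`OC` lines) from the
#' EMBL text served by the ENA browser API.
#'
#' @param text character vector of response lines (or one string).
#' @return list with `lineage` ranks, `genus`, `species`, or `NULL` when the
#'   text carries no taxonomy.
#' @export
parse_ena_embl <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  os <- sub("^OS\\s+", "", grep("^OS\\s", lines, value = TRUE))
  oc <- sub("^OC\\s+", "", grep("^OC\\s", lines, value = TRUE))
  if (length(os) == 0L) return(NULL)
  organism <- trimws(os[1L])
  ranks <- character()
  if (length(oc) > 0L) {
    joined <- paste(oc, collapse = " ")
    joined <- sub("\\.\\s*$", "", joined)
    ranks <- trimws(strsplit(joined, ";", fixed = TRUE)[[1L]])
    ranks <- ranks[nzchar(ranks)]
  }
  bn <- parse_binomial(organism)
  list(lineage = c(ranks, organism), genus = bn$genus, species = bn$species)
}

#' Parse an NCBI Entrez efetch GBSeq XML response into a lineage
#'
#' Extracts `GBSeq_organism` and `GBSeq_taxonomy` from the XML served by
#' `efetch` (db=nuccore, rettype=gb, retmode=xml).
#'
#' @param text XML response text.
#' @return list with `lineage` ranks, `genus`, `species`, or `NULL`.
#' @export
parse_ncbi_gb_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(paste(text, collapse = "\n")),
                  error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  organism <- xml2::xml_text(xml2::xml_find_first(doc, ".//GBSeq_organism"))
  taxonomy <- xml2::xml_text(xml2::xml_find_first(doc, ".//GBSeq_taxonomy"))
  if (is.na(organism) || !nzchar(organism)) return(NULL)
  ranks <- character()
  if (!is.na(taxonomy) && nzchar(taxonomy)) {
    ranks <- trimws(strsplit(taxonomy, ";", fixed = TRUE)[[1L]])
    ranks <- ranks[nzchar(ranks)]
  }
  bn <- parse_binomial(organism)
  list(lineage = c(ranks, organism), genus = bn$genus, species = bn$species)
}

# --- network adapter -------------------------------------------------------

the <- new.env(parent = emptyenv())
the$last_request <- 0

# polite spacing: at most 3 requests per second
rate_limit <- function() {
  wait <- the$last_request + 1 / 3 - as.numeric(Sys.time())
  if (wait > 0) Sys.sleep(wait)
  the$last_request <- as.numeric(Sys.time())
}

http_get <- function(url) {
  rate_limit()
  con <- url(url, open = "rb",
             headers = c(`User-Agent` = "asvrefdb (lineage verification)"))
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

#' Default lineage fetchers (ENA first, NCBI Entrez fallback)
#'
#' Each fetcher maps an accession to a lineage list (as from
#' [parse_ena_embl()]) or `NULL` on a miss. Isolated here so tests can inject
#' mock fetchers and so endpoint changes touch one place.
#'
#' @return named list of functions `ena` and `ncbi`.
#' @export
default_fetchers <- function() {
  list(
    ena = function(accession) {
      txt <- http_get(paste0("https://www.ebi.ac.uk/ena/browser/api/embl/",
                             utils::URLencode(accession, reserved = TRUE)))
      parse_ena_embl(txt)
    },
    ncbi = function(accession) {
      txt <- http_get(paste0(
        "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
        "?db=nuccore&rettype=gb&retmode=xml&id=",
        utils::URLencode(accession, reserved = TRUE)))
      parse_ncbi_gb_xml(txt)
    }
  )
}

with_backoff <- function(fn, attempts = 3L, base_delay = 0.5) {
  for (k in seq_len(attempts)) {
    out <- tryCatch(fn(), error = function(e) structure(list(), class = "try-miss"))
    if (!inherits(out, "try-miss")) return(out)
    if (k < attempts) Sys.sleep(base_delay * 2^(k - 1L))
  }
  NULL
}

#' Resolve the lineage of one accession
#'
#' Cache hits are returned as-is. Otherwise, with `network = TRUE`, the ENA
#' API is queried first and NCBI Entrez on an ENA miss; the outcome
#' (including a failure) is stored in the cache. Transport errors are retried
#' with exponential backoff (3 attempts) and then recorded as failed — a
#' lookup never aborts a build. With `network = FALSE` the header-derived
#' lineage is returned marked `unverified` (and is not cached, so a later
#' online run can still verify it).
#'
#' @param accession accession to resolve.
#' @param cache a [lineage_cache()].
#' @param network allow network lookups.
#' @param header_lineage optional list(`lineage`, `genus`, `species`) parsed
#'   from the FASTA header, used offline and as the last fallback.
#' @param fetchers adapter list as from [default_fetchers()].
#' @return list with `lineage`, `genus`, `species` and `verified` (one of
#'   `"unverified"`, `"ena"`, `"ncbi"`, `"failed"`).
#' @export
resolve_lineage <- function(accession, cache = lineage_cache(),
                            network = FALSE, header_lineage = NULL,
                            fetchers = default_fetchers()) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession), inherits(cache, "lineage_cache"))
  hit <- cache_get(cache, accession)
  if (!is.null(hit)) {
    return(list(lineage = hit$lineage, genus = hit$genus,
                species = hit$species, verified = hit$source))
  }
  if (!network) {
    return(list(lineage = header_lineage$lineage %||% character(),
                genus = header_lineage$genus %||% NA_character_,
                species = header_lineage$species %||% NA_character_,
                verified = "unverified"))
  }
  res <- with_backoff(function() fetchers$ena(accession))
  source <- "ena"
  if (is.null(res)) {
    res <- with_backoff(function() fetchers$ncbi(accession))
    source <- "ncbi"
  }
  if (is.null(res)) {
    res <- list(lineage = header_lineage$lineage %||% character(),
                genus = header_lineage$genus %||% NA_character_,
                species = header_lineage$species %||% NA_character_)
    source <- "failed"
  }
  cache_put(cache, accession, list(lineage = res$lineage, genus = res$genus,
                                   species = res$species, source = source))
  list(lineage = res$lineage, genus = res$genus, species = res$species,
       verified = source)
}

#' Verify the lineages of a record table
#'
#' Applies [resolve_lineage()] to every record; when the API lineage
#' disagrees with the header-derived one, the API wins (the point of the step
#' is verification) and the discrepancy is noted in the returned attribute
#' `n_discrepant`.
#'
#' @param records data.frame from [read_fasta()].
#' @inheritParams resolve_lineage
#' @return the records with `lineage`, `genus`, `species` and `verified`
#'   updated.
#' @export
verify_records <- function(records, cache = lineage_cache(), network = FALSE,
                           fetchers = default_fetchers()) {
  stopifnot(is.data.frame(records))
  n_discrepant <- 0L
  for (i in seq_len(nrow(records))) {
    header <- list(
      lineage = if (is.na(records$lineage[i])) character()
                else strsplit(records$lineage[i], ";", fixed = TRUE)[[1L]],
      genus = records$genus[i], species = records$species[i]
    )
    res <- resolve_lineage(records$accession[i], cache = cache,
                           network = network, header_lineage = header,
                           fetchers = fetchers)
    if (res$verified %in% c("ena", "ncbi")) {
      if (!is.na(records$species[i]) && !is.na(res$species) &&
          records$species[i] != res$species) {
        n_discrepant <- n_discrepant + 1L
      }
      records$lineage[i] <- if (length(res$lineage) == 0L) NA_character_
                            else paste(res$lineage, collapse = ";")
      records$genus[i] <- res$genus
      records$species[i] <- res$species
    }
    records$verified[i] <- res$verified
  }
  if (n_discrepant > 0L) {
    message("verify_records: API lineage overruled the FASTA header for ",
            n_discrepant, " record(s)")
  }
  attr(records, "n_discrepant") <- n_discrepant
  records
}
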