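# shared builders for pipeline tests

test_primers <- function(threshold = 1, keep_primers = FALSE) {
  primer_pair("CCGGTCACTTGATCTACCAG", "ATGACGGTGACATAGTAGCG",
              threshold = threshold, keep_primers = keep_primers)
}

# template with exact planted sites: flank + F + insert + revcomp(R) + flank
planted_template <- function(insert, primers, left = "AAAAAAAA",
                             right = "TTTTTTTT") {
  paste0(left, primers$forward, insert,
         reverse_complement(primers$reverse), right)
}

# a small record table in the shape read_fasta() returns
record_table <- function(accession, species, sequence) {
  genus <- vapply(strsplit(species, " ", fixed = TRUE), `[[`, character(1L),
                  1L)
  data.frame(accession = accession, description = species,
             sequence = sequence, source_db = "generic",
             lineage = NA_character_, genus = genus, species = species,
             verified = "unverified", stringsAsFactors = FALSE)
}

# build -> filter -> group on a generated fixture FASTA
run_pipeline <- function(fasta, genus, primers,
                         patterns = default_exclude_patterns()) {
  rec <- read_fasta(fasta, "generic")
  make_sa_groups(filter_taxa(build_database(rec, genus, primers), patterns))
}
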