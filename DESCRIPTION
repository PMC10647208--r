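Package: asvrefdb
Title: Genus-Specific Amplicon Sequence Variant Reference Databases via
    Simulated PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genus-specific, primer-specific reference databases of
    amplicon sequence variants (ASVs) from FASTA files downloaded from public
    sequence databases (SILVA, UNITE, ENA, RNAcentral, NCBI, DDBJ). PCR
    amplification is simulated on every source sequence by glocal affine-gap
    alignment of IUPAC-degenerate primers (match +1, mismatch 0, gap open -1,
    gap extend -0.5) with a 3'-anchor rule; identical amplicons carried by
    several species are grouped as Shared Amplicons (SA) instead of being
    collapsed to a lossy consensus. Databases from different sources can be
    merged, and the result is exported as a reference FASTA plus taxonomy TSV
    pair suitable for exact-match (100% identity, 100% coverage) secondary
    taxonomic assignment in amplicon pipelines. Includes a synthetic-fixture
    generator with planted primer sites and known ground truth, an offline
    cache-backed lineage resolver (ENA first, NCBI Entrez fallback), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
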