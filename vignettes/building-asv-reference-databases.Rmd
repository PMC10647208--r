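---
title: "Building genus-specific ASV reference databases by simulated PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building genus-specific ASV reference databases by simulated PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvrefdb)
```

## The model

An amplicon sequencing experiment observes, for each template molecule, the
exact sequence between (or including) a primer pair. A reference database
for exact-match assignment must therefore hold *amplicons*, not full-length
reference sequences: two species with distinct 18S or EF1α genes may still
be indistinguishable over the amplified window. `asvrefdb` models this by
simulating the PCR on every source sequence and collapsing the results:

- a **variant** is one distinct amplicon sequence;
- its **taxon** is the single species that produced it, the species complex
  it belongs to, or — when several species yield the identical amplicon —
  a **Shared Amplicon (SA)** group listing all of them.

The SA construct is the scientific point: a consensus label
("*Fusarium* spp.") erases the candidate list, whereas `Fusarium_SA1 =
{F. asiaticum, F. graminearum, ...}` preserves it inside the taxonomy
string, at no cost to the assignment machinery.

## Amplification simulation

### Alignment and scoring

Primer binding is scored by a glocal (fitting) affine-gap alignment: the
*entire* primer is aligned against a local window of the template, with free
leading and trailing template. Scores are match = +1, mismatch = 0,
gap open = −1, gap extend = −0.5. The scheme deliberately favours matches
and mismatches over gaps — an annealing primer tolerates isolated
mismatches far better than bulges. Anchoring the full primer (rather than a
fully local alignment) reflects the chemistry and makes "the last three
bases at the 3′ end" well defined for every hit.

All attainable scores are multiples of 0.5 and are represented exactly in
floating point, so equality comparisons in the dynamic program and the
tie-break logic involve no tolerance. Equal-score hits resolve
deterministically to the smallest start, then the shortest span. The kernel
is implemented in C++ (Gotoh three-state recurrence); the test suite holds
an independent plain-R implementation of the same DP, itself validated
against exhaustive alignment enumeration on tiny instances, and the two are
compared on hundreds of randomized cases including degenerate primers.

### IUPAC ambiguity

Ambiguity codes in the *primer* are part of its design (e.g. 515FB
`GTGYCAGCMGCCGCGGTAA`) and match any template base in their expansion set.
Ambiguity in the *template* is missing information, not degeneracy, and
scores as a mismatch: an N-rich reference stretch should fail the 3′ rule
rather than amplify against every primer. This asymmetry is intentional and
conservative.

### Acceptance of a hit

A candidate amplicon is accepted only if

1. both primer alignments reach `threshold × primer length`, and
2. each primer's final three 3′ alignment columns are matches — no
   mismatch, no gap (the 3′-anchor rule). For the reverse primer, aligned
   as its reverse complement, the 3′ end corresponds to the *first* three
   template-orientation columns. Gaps in these columns are rejected on the
   same footing as mismatches, since neither leaves a correctly paired 3′
   terminus for the polymerase to extend.

The threshold is expressed as a fraction of the primer's maximum score
(its length) rather than an absolute score, because absolute scores are not
comparable across primers of different lengths; the default of 0.9 admits
up to two internal mismatches on a 20-mer. Public-database entries are
deposited in either orientation, so when the forward pass finds nothing the
reverse complement of the template is scanned (`try_reverse_strand`,
default on).

Only the single best forward and reverse hit is used per record, so a
template carrying the target locus twice yields one amplicon; multi-copy
loci with divergent paralogues are a known limitation.

## Database construction

`build_database()` keeps records of the target genus (case-insensitive,
whitespace-trimmed), amplifies each and collapses identical amplicons,
accumulating taxa and accessions. Collapsing happens *before* taxonomy
filtering; the two orders differ only in filter-log counts, never in the
final entries. `filter_taxa()` removes species labels matching configurable
patterns (defaults: epithet "sp.", epithet beginning "aff." or "cf.") and
deletes entries left with no taxa. Sub-species annotations (strain ids,
formae speciales, varieties) are truncated at the species epithet when
headers are parsed, since the taxon model is species-level; "... complex"
names are kept intact as single taxa.

`make_sa_groups()` assigns `Genus_SpeciesName` to single-taxon entries and
`Genus_SAn` to multi-taxon entries. SA numbers run 1..K in lexicographic
order of amplicon sequence — the numbering had to be fixed by *some* rule,
and sequence order is deterministic and independent of input order, so the
same content always yields the same names. `merge_databases()` unions
entries by sequence and renumbers all SA groups on the union: numbering is
database-scoped, and stable numbering across merges would require a central
registry that cannot exist for independently built databases.

Exports are sorted by MD5 feature ID and carry no timestamps, so identical
content produces byte-identical reference files; run metadata (provenance,
filter logs) lives only in the JSON database document, and
`db_canonical()` serializes the scientific content alone for comparisons.

## Lineage verification

Source-database headers are the primary lineage source; accession-based
verification queries the ENA browser API (EMBL flat text) and falls back to
NCBI Entrez (GBSeq XML). When an API lineage disagrees with the header, the
API wins — the step exists to *verify* — and the discrepancy is counted.
Lookups go through a mandatory file-backed, append-only cache; transport
failures are retried three times with exponential backoff and then recorded
as failed rather than aborting a build. Requests are spaced to at most 3/s
with an identifying User-Agent. With `network = FALSE` (the default, and
the CLI's behaviour unless `--online` is given) the header lineage is used
unverified, and a fully offline run is guaranteed to produce output
identical to a run whose cache already contains every accession.

## The synthetic-fixture generator

`generate_fixture()` emulates exactly the structure the pipeline must
recover: records assembled as
`flank + forward site + insert + revcomp(reverse) site + flank`, with

- degenerate primer positions resolved uniformly at random *per record*, so
  ambiguity matching is exercised rather than bypassed;
- chosen species pairs sharing one insert (overlapping pairs merge
  transitively, so expected SA groups are the connected components of the
  pair graph);
- planted primer mismatches at stated distances from the 3′ end;
- off-genus and genus-only ("sp.") records at configurable fractions;
- random segments screened against full-score primer sites on either
  strand, regenerated on collision, so no spurious amplicon can appear.

Defaults (6 species, 2 records per species, one shared pair, 60 nt inserts,
25 nt flanks, 10% off-genus, 10% "sp.") are sized so that every filter in
the pipeline has work to do while a single fixture stays small enough to
align in milliseconds. The generator computes its expected database —
entries, SA membership, filter removals — from its own plan, never by
calling the pipeline, so recovery tests compare two independent routes.

What the generator does *not* emulate: phylogenetically realistic sequence
divergence, length variation among amplicons of one locus, chimeras,
sequencing errors, species-complex labels, and the taxonomic annotation
errors common in general-purpose repositories. Passing tests therefore
demonstrate the correctness of the amplification, collapsing, filtering,
grouping, merging and export logic on clean planted structure — not the
ecological quality of databases built from any particular public corpus,
which depends on the corpus' own curation.

## Numerical and degenerate-input choices

- Scores are exact on a 0.5 grid; no epsilon comparisons in the DP.
- Empty template, non-IUPAC characters: validation errors naming the
  position; primers must be ≥ 10 nt and valid IUPAC.
- Abutting or overlapping primer hits with `keep_primers = FALSE` produce
  no amplicon (empty insert) and are logged as degenerate.
- Zero amplifiable records produce an *empty database plus a prominent
  message*, not an error — an empty result is a legitimate finding about a
  primer pair; exporting an empty database is the error.
- Duplicate accessions in one file resolve last-wins with a warning;
  records with alphabet violations are dropped and counted.
- Entries, SA groups and exports are canonically ordered (bytewise radix
  order of sequences / feature IDs) at every stage.

## Test problem sizes

The property suite runs the alignment kernel against the independent DP
oracle on 220 randomized instances (primers ≤ 25 nt, templates ≤ 200 nt,
degenerate positions included), checks planted-structure recovery on 50
randomized fixture specifications (3–8 species, 1–3 records each, 0–3
shared pairs, seeds 1–50), and exercises the 3′-anchor rule on fixtures
planting mismatches at 3′ positions 1–3 of both primers. These sizes give
full coverage of the combinatorial behaviour (shared/unshared, overlapping
pairs, filtered and off-genus records) while the whole suite completes in
well under a minute of alignment work.

## Known limitations

- One genus per database; inter-genus conflicts are out of scope, so for
  broad-range primers the database is meant as a *secondary* step after a
  genus-level classification.
- One amplicon per source record (single best hit per primer).
- No thermodynamic model: annealing is score-based, with no melting
  temperature, secondary structure or primer-dimer considerations.
- Exact-match assignment presumes high-quality denoised variants
  (Illumina-class error profiles); noisy long-read data will simply fail to
  match rather than mis-assign.
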