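# Named primer presets (5'->3', IUPAC ambiguity codes allowed).
# 515FB/926R: bacterial 16S rRNA V4V5; BITS/B58S3: fungal ITS1;
# Fa-150/Ra-2: Fusarium elongation factor 1-alpha.
515FB: GTGYCAGCMGCCGCGGTAA
926R: CCGYCAATTYMTTTRAGTTT
BITS: ACCTGCGGARGGATCA
B58S3: GAGATCCRTTGYTRAAAGTT
Fa-150: CCGGTCACTTGATCTACCAG
Ra-2: ATGACGGTGACATAGTAGCG
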