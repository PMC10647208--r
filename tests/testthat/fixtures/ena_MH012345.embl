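ID   MH012345; SV 1; linear; genomic DNA; STD; FUN; 680 BP.
AC   MH012345;
DE   Fusarium oxysporum strain X translation elongation factor 1-alpha
DE   (EF1a) gene, partial cds.
OS   Fusarium oxysporum
OC   Eukaryota; Fungi; Dikarya; Ascomycota; Pezizomycotina; Sordariomycetes;
OC   Hypocreomycetidae; Hypocreales; Nectriaceae; Fusarium.
SQ   Sequence 680 BP;
     ccggtcactt gatctaccag                                              20
//
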