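<?xml version="1.0" encoding="UTF-8"?>
<GBSet>
  <GBSeq>
    <GBSeq_locus>MH012346</GBSeq_locus>
    <GBSeq_organism>Fusarium solani</GBSeq_organism>
    <GBSeq_taxonomy>Eukaryota; Fungi; Dikarya; Ascomycota; Pezizomycotina; Sordariomycetes; Hypocreomycetidae; Hypocreales; Nectriaceae; Fusarium</GBSeq_taxonomy>
  </GBSeq>
</GBSet>
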