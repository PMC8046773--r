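# SYNTHETIC example per-allele effects on leukocyte telomere length (bp).
# These are placeholder values in the range typical of telomere GWAS loci,
# bundled so the simulator, examples and tests can run. They are NOT
# published estimates; supply your own weights for real analyses.
weights:
  rs11125529: 65
  rs6772228: 120
  rs10936599: 117
  rs7675998: 74
  rs2736100: 78
  rs9420907: 69
  rs3027234: 75
  rs8105767: 48
  rs412658: 58
  rs6028466: 60
  rs755017: 62
weight_se:
  rs11125529: 15
  rs6772228: 28
  rs10936599: 16
  rs7675998: 15
  rs2736100: 12
  rs9420907: 14
  rs3027234: 17
  rs8105767: 11
  rs412658: 12
  rs6028466: 18
  rs755017: 16
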