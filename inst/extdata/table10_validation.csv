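run,EF,zone_xanthomonas,zone_colletotrichum,zone_fusarium,zone_aspergillus
1,97.50,43.00,40.33,37.00,44.85
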