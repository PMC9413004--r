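run,EF,zone_xanthomonas,zone_colletotrichum,zone_fusarium,zone_aspergillus
1,98.60,42.00,40.33,36.33,36.33
2,97.63,42.67,34.67,37.00,32.33
3,76.63,22.33,29.33,35.33,41.00
4,89.23,43.33,35.00,35.00,41.67
5,76.06,43.00,35.00,35.00,39.33
6,73.76,41.33,33.00,34.33,35.33
7,97.27,40.33,41.00,36.67,44.33
8,97.60,40.00,38.33,37.67,41.33
9,79.83,43.67,39.33,34.67,40.67
10,95.55,29.00,32.00,38.00,26.00
11,86.36,31.00,32.67,36.67,33.00
12,75.27,32.33,32.67,35.00,29.67
13,94.19,40.00,41.00,37.00,37.33
14,83.35,37.33,34.67,35.67,35.33
15,63.10,31.33,32.00,31.33,40.67
16,93.90,40.00,35.00,35.33,40.33
17,91.56,44.67,35.33,34.67,40.00
18,72.97,34.00,31.67,34.00,43.67
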