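run,EF,SN
1,98.60,39.8776
2,97.63,39.7918
3,76.63,37.6883
4,89.23,39.0104
5,76.06,37.6230
6,73.76,37.3566
7,97.27,39.7598
8,97.60,39.7886
9,79.83,38.0431
10,95.55,39.6045
11,86.36,38.7263
12,75.27,37.5323
13,94.19,39.4797
14,83.35,38.4176
15,63.10,36.0008
16,93.90,39.4531
17,91.56,39.2346
18,72.97,37.2631
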