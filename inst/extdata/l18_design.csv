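run,A,B,C,D,E
1,1,1,1,1,1
2,1,2,2,2,2
3,1,3,3,3,3
4,2,1,1,2,2
5,2,2,2,3,3
6,2,3,3,1,1
7,3,1,2,1,3
8,3,2,3,2,1
9,3,3,1,3,2
10,1,1,3,3,2
11,1,2,1,1,3
12,1,3,2,2,1
13,2,1,2,3,1
14,2,2,3,1,2
15,2,3,1,2,3
16,3,1,3,2,3
17,3,2,1,3,1
18,3,3,2,1,2
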