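network17,network7,weight
1,1,1
2,1,1
3,2,1
4,2,1
5,3,1
6,3,1
7,4,1
8,4,1
9,5,1
10,5,1
11,6,0.5
11,7,0.5
12,6,1
13,7,1
14,7,1
15,7,1
16,7,1
17,7,1
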