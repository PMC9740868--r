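run,predicted_mg_g
1,44.41
2,51.65
3,43.67
4,41.62
5,53.04
6,44.11
7,48.24
8,39.77
9,53.55
10,46.59
11,50.21
12,55.58
13,49.58
14,55.58
15,48.99
16,46.73
17,50.71
18,55.58
19,52.54
20,47.21
21,55.58
22,47.79
23,44.48
24,40.69
25,53.30
26,47.35
27,51.10
28,44.45
29,55.58
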