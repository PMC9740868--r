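run,temperature_C,time_h,alkali_mol_L,ratio_mL_g,response_mg_g
1,60,2,0.25,50,44.83
2,70,3,0.25,70,51.46
3,60,4,0.3,60,43.01
4,60,3,0.3,50,42.09
5,70,2,0.25,60,52.23
6,50,4,0.25,60,45.07
7,50,2,0.25,60,46.79
8,50,3,0.25,50,40.55
9,70,4,0.25,60,55.15
10,50,3,0.2,60,45.02
11,60,2,0.2,60,51.47
12,60,3,0.25,60,56.18
13,70,3,0.25,50,48.47
14,60,3,0.25,60,54.38
15,70,3,0.3,60,49.81
16,60,4,0.25,50,45.61
17,60,4,0.2,60,51.11
18,60,3,0.25,60,56.36
19,70,3,0.2,60,52.22
20,50,3,0.25,70,48.91
21,60,3,0.25,60,55.92
22,60,2,0.3,60,47.99
23,60,3,0.3,70,44.07
24,50,3,0.3,60,40.26
25,60,2,0.25,70,53.68
26,60,4,0.25,70,46.18
27,60,3,0.2,70,50.77
28,60,3,0.2,50,45.01
29,60,3,0.25,60,55.08
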