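residue,content_pct
Asp,5.302
Thr,2.384
Ser,2.262
Glu,12.378
Gly,2.602
Ala,2.948
Val,3.854
Met,0.460
Ile,2.406
Leu,3.644
Tyr,1.806
Phe,3.166
Lys,2.900
His,1.498
Arg,2.590
Pro,3.202
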