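r_mm,phi_an
1.0,1.107
1.5,1.345
2.0,1.313
2.5,1.406
3.0,1.277
3.5,1.208
4.0,1.178
4.5,1.167
5.0,1.165
5.5,1.179
6.0,1.205
6.5,1.251
7.0,1.310
7.5,1.399
8.0,1.522
8.5,1.708
9.0,1.987
9.5,2.374
10.0,2.668
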