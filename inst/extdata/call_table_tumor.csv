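patient_id,specimen,arms_g12v,arms_g12d,ss,ddpcr
1,tumor,G12V,NEG,wt_G12V,G12V
2,tumor,NEG,G12D,wt_G12D,G12D
3,tumor,G12V,NEG,wt_G12V,G12V
4,tumor,NEG,NEG,wt,wt
5,tumor,NEG,G12D,wt_G12D,G12D
6,tumor,NEG,G12D,wt,G12D
7,tumor,NEG,G12D,wt,wt
8,tumor,G12V,NEG,wt_G12V,G12V
9,tumor,NA,NA,wt_G12V,NA
10,tumor,NEG,NEG,wt,NA
11,tumor,NEG,G12D,wt_G12D,G12D
12,tumor,G12V,NEG,wt,G12V
13,tumor,G12V,NEG,wt_G12V,NA
14,tumor,NEG,NEG,wt,wt
15,tumor,NEG,NEG,wt_G12R,G12R
16,tumor,NEG,NEG,wt_G12R,G12R
17,tumor,NEG,G12D,wt_G12D,G12D
18,tumor,G12V,NEG,wt_G12V,G12V
19,tumor,G12V,NEG,wt_G12V,G12V
20,tumor,NEG,G12D,wt_G12D,G12D
21,tumor,G12V,NEG,wt_G12V,G12V
22,tumor,NEG,G12D,wt_G12D,G12D
23,tumor,NEG,G12D,wt_G12D,G12D
24,tumor,NEG,G12D,wt_G12D,NA
25,tumor,NEG,NEG,wt_G12R,G12R
26,tumor,NEG,NEG,wt,wt
27,tumor,G12V,NEG,wt_G12V,G12V
28,tumor,NEG,G12D,wt_G12D,G12D
29,tumor,G12V,NEG,wt_G12V,G12V
30,tumor,NEG,G12D,wt_G12D,G12D
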