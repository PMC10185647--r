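patient_id,specimen,arms_g12v,arms_g12d,ss,ddpcr
1,plasma,NEG,NEG,wt,NA
2,plasma,NEG,NEG,wt,wt
3,plasma,NEG,NEG,NA,wt
4,plasma,NEG,NEG,UNREADABLE,wt
5,plasma,NEG,NEG,UNREADABLE,wt
6,plasma,NEG,NEG,wt,wt
7,plasma,NEG,G12D,wt,wt
8,plasma,G12V,NEG,UNREADABLE,G12V
9,plasma,G12V,NEG,wt_G12V,G12V
10,plasma,NA,NA,NA,NA
11,plasma,NEG,NEG,wt,wt
12,plasma,NEG,NEG,NA,wt
13,plasma,NEG,NEG,NA,wt
14,plasma,NEG,NEG,UNREADABLE,wt
15,plasma,NA,NA,NA,NA
16,plasma,NEG,NEG,wt,G12R
17,plasma,NEG,NA,NA,wt
18,plasma,G12V,NA,wt,G12V
19,plasma,NEG,NA,NA,NA
20,plasma,NEG,NEG,wt,wt
21,plasma,NEG,NA,UNREADABLE,wt
22,plasma,NEG,NEG,wt,wt
23,plasma,NEG,NA,UNREADABLE,G12D
24,plasma,NEG,NEG,UNREADABLE,wt
25,plasma,NEG,NEG,UNREADABLE,G12R
26,plasma,NEG,NEG,wt,wt
27,plasma,NEG,NEG,wt,wt
28,plasma,NEG,NEG,wt,wt
29,plasma,NEG,NEG,UNREADABLE,wt
30,plasma,NEG,NEG,UNREADABLE,wt
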