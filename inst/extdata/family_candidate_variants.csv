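family,tier,gene,rsid,chrom,pos,aa_change,effect,impact,sift,polyphen2_hdiv,phylop,phastcons,af_global,af_east_asian,af_korean
FamA,common,COL6A6,rs16830494,chr3,130361856,R1739Q,NON_SYNONYMOUS_CODING,MODERATE,0.04,0.272,1.703,0.995,0.12,0.19,0.188
FamA,common,ANKRD35,rs11579366,chr1,145562293,E661Q,NON_SYNONYMOUS_CODING,MODERATE,0.38,0.971,5.285,1,0.39,0.26,0.233
FamA,common,TUFT1,rs3828054,chr1,151512895,Q18R,NON_SYNONYMOUS_CODING,MODERATE,0.77,0.688,1.688,0.288,0.1,0.03,0.047
FamA,common,TMEM175,rs34311866,chr4,951947,M393T,NON_SYNONYMOUS_CODING,MODERATE,0.01,0,1.299,0.999,0.12,0.12,0.155
FamA,common,EDN1,rs5370,chr6,12296255,K198N,NON_SYNONYMOUS_CODING,MODERATE,0.08,0.454,0.049,0.001,0.21,0.28,0.258
FamA,common,NRAP,rs2270182,chr10,115392919,N519I,NON_SYNONYMOUS_CODING,MODERATE,0.19,0.958,2.477,1,0.26,0.2,0.205
FamA,common,HGFAC,rs16844401,chr4,3449652,R509H,NON_SYNONYMOUS_CODING,MODERATE,0.22,0.943,2.662,0.593,0.07,0.1,0.115
FamA,common,UNC93A,rs2235197,chr6,167709702,W151*,STOP_GAINED,HIGH,,,4.525,1,0.1,0.15,0.163
FamA,common,ABCA13,rs1771229,chr7,48313881,F1540L,NON_SYNONYMOUS_CODING,MODERATE,,0.997,2.325,0.614,0.11,0.17,0.255
FamA,common,SSPO,rs1005603,chr7,149516881,S4028I,NON_SYNONYMOUS_CODING,MODERATE,,,,,0.2,0.19,0.181
FamA,common,TTC40,rs12781609,chr10,134748331,S264N,NON_SYNONYMOUS_CODING,MODERATE,,,,,0.37,0.36,0.412
FamA,rare,DNAH17,,chr17,76567792,I204M,NON_SYNONYMOUS_CODING,MODERATE,0.11,,1.926,0.992,,,
FamA,rare,COL6A6,rs200963433,chr3,130289976,R906C,NON_SYNONYMOUS_CODING,MODERATE,0,1,4.596,1,0.0014,0.01,0.017
FamB,common,COL6A6,rs59021909,chr3,130285929,P556S,NON_SYNONYMOUS_CODING,MODERATE,0.11,0.999,2.136,0.997,0.09,0.08,0.119
FamB,common,UVSSA,rs2276904,chr4,1349029,R391H,NON_SYNONYMOUS_CODING,MODERATE,,,,,0.23,0.42,0.374
FamB,common,TUFT1,rs3828054,chr1,151512895,Q18R,NON_SYNONYMOUS_CODING,MODERATE,0.77,0.688,1.688,0.763,0.1,0.03,0.047
FamB,common,TMEM175,rs34311866,chr4,951947,M393T,NON_SYNONYMOUS_CODING,MODERATE,0.01,0,1.299,0.563,0.12,0.12,0.155
FamB,common,EDN1,rs5370,chr6,12296255,K198N,NON_SYNONYMOUS_CODING,MODERATE,0.08,0.454,0.049,0.895,0.21,0.28,0.258
FamB,common,NRAP,rs868738,chr10,115381747,R884C,NON_SYNONYMOUS_CODING,MODERATE,0.01,0.986,4.833,1,0.24,0.17,0.198
FamB,rare,CDX1,rs370852694,chr5,149546819,A127E,NON_SYNONYMOUS_CODING,MODERATE,0.87,0.458,1.235,0.996,,,0.027
FamB,rare,DNAH17,rs78098467,chr17,76510974,A1332V,NON_SYNONYMOUS_CODING,MODERATE,0.6,,4.052,1,0.01,0.04,0.037
FamB,rare,ANKRD35,rs146839643,chr1,145560094,C194R,NON_SYNONYMOUS_CODING,MODERATE,0.01,1,3.419,1,0.0037,0.01,0.016
FamC,common,UVSSA,rs2276904,chr4,1349029,R391H,NON_SYNONYMOUS_CODING,MODERATE,,,,,0.23,0.42,0.374
FamC,common,HGFAC,rs3748034,chr4,3446091,A218S,NON_SYNONYMOUS_CODING,MODERATE,0.38,0.659,2,1,0.15,0.28,0.305
FamC,common,UNC93A,rs2235197,chr6,167709702,W151*,STOP_GAINED,HIGH,,,4.525,1,0.1,0.15,0.163
FamC,common,ABCA13,rs17712299,chr7,48313881,F1540L,NON_SYNONYMOUS_CODING,MODERATE,,0.997,2.325,0.85,0.11,0.17,0.255
FamC,common,SSPO,rs1005603,chr7,149516881,S4028I,NON_SYNONYMOUS_CODING,MODERATE,,,,1,0.2,0.19,0.181
FamC,common,TTC40,,chr10,134679632,T1596M,NON_SYNONYMOUS_CODING,MODERATE,,,,,,,
FamC,rare,COL6A6,rs200963433,chr3,130289976,R906C,NON_SYNONYMOUS_CODING,MODERATE,0,1,4.596,1,0.0014,0.01,0.017
FamC,rare,CDX1,rs370852694,chr5,149546819,A127E,NON_SYNONYMOUS_CODING,MODERATE,0.87,0.458,1.235,0.996,,,0.027
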