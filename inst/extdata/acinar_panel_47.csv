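gene,refseq,rank_primary,rank_secondary,rank_3d,fold_decrease_3d,shrna_outcome
ACE2,NM_021804,22,30,11,5.169,lethal
ADCY4,NM_139247,44,17,44,0.878,lethal
BDKRB2,NM_000623,28,44,31,2.484,growth-postselection
BST1,NM_004334,7,6,14,4.406,lethal
CD79A,NM_001783,13,16,33,2.366,growth-postselection
COL9A3,NM_001853,16,4,22,3.489,lethal
CTNNA1,NM_001903,37,29,18,4.047,lethal
EFNA4,NM_005227,38,37,5,7.338,growth-postselection
FIT1,NM_203402,4,22,NA,NA,growth-postselection
FLJ30634,NM_153014,15,30,17,4.055,growth-postselection
FLOT2,NM_004475,23,31,41,1.618,lethal
FZD2,NM_001466,6,25,19,3.712,lethal
GPR182,NM_007264,9,20,32,2.483,growth-postselection
GPR39,NM_001508,10,22,26,3.159,growth-postselection
GPR80,NM_080818,32,14,27,3.137,lethal
HSD17B2,NM_002153,27,38,2,27.328,lethal
KCNJ5,NM_000890,3,35,42,1.494,growth-postselection
KTELC1,NM_020231,8,17,NA,NA,growth-postselection
LGALS1,NM_002305,36,7,16,4.120,growth-postselection
LPAR3,NM_012152,1,5,20,3.530,growth-postselection
LTBP3,NM_021070,39,28,9,5.291,growth-postselection
MMP24,NM_006690,40,5,8,5.447,growth-postselection
MMP28,NM_024302,18,25,37,2.075,lethal
NKAIN4,NM_152864,20,9,21,3.505,lethal
NPTX1,NM_002522,45,18,6,7.082,lethal
NTN1,NM_004822,47,22,10,5.175,growth-postselection
NTN2L,NM_006181,5,30,13,4.691,growth-postselection
OPRS1,NM_005866,29,26,24,3.243,lethal
PARD3,NM_019619,30,31,15,4.221,lethal
PCDHB13,NM_018933,46,27,43,1.214,growth-postselection
PDCD1,NM_005018,21,36,28,2.997,growth-postselection
PLA2G2F,NM_022819,19,22,38,2.028,lethal
PLUNC,NM_016583,31,30,23,3.280,growth-postselection
PLXNA2,NM_025179,2,24,29,2.780,growth-postselection
PROCR,NM_006404,35,36,1,31.637,growth-postselection
RHCE,NM_020485,42,31,35,2.209,lethal
RIPK2,NM_003821,41,23,NA,NA,lethal
ROBO3,NM_022370,11,35,39,2.012,growth-postselection
SAA1,NM_000331,14,21,12,5.167,lethal
SCARB2,NM_005506,34,9,34,2.317,lethal
SEMA3C,NM_006379,12,25,40,1.936,growth-postselection
SERPINH1,NM_001235,26,32,25,3.187,lethal
SLC6A4,NM_001045,17,29,36,2.142,growth-postselection
SNN,NM_003498,24,30,3,11.523,lethal
TMEM14C,NM_016462,33,32,7,5.884,lethal
TMEM9B,NM_020644,43,23,30,2.556,lethal
TUFT1,NM_020127,25,20,4,7.399,lethal
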