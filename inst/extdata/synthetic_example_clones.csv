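clone_id,donor_id,subset,culture,division,G,M,L,DC1,DC2,pDC
HSC_0001,D01,HSC,MPFSG,,0,0,0,0,0,0
HSC_0002,D02,HSC,MPFSG,,3,59,116,2,40,21
HSC_0003,D02,HSC,MPFSG,,80,101,118,114,247,137
HSC_0004,D02,HSC,MPFSG,,66,8,1,13,0,30
CMP_0001,D02,CMP,MPFSG,,23,15,5,18,7,26
CMP_0002,D01,CMP,MPFSG,,0,0,0,0,0,0
CMP_0003,D02,CMP,MPFSG,,0,17,1,11,6,0
CMP_0004,D01,CMP,MPFSG,,56,9,34,11,15,14
CDP_0001,D02,CDP,MPFSG,,317,316,3,1055,264,163
CDP_0002,D02,CDP,MPFSG,,35,198,6,25,195,65
CDP_0003,D02,CDP,MPFSG,,81,164,29,151,67,1590
CDP_0004,D01,CDP,MPFSG,,23,9,5,14,14,2
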