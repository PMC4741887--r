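gene
KLF5
BIRC5
CCND1
CCNE1
CDC20
CDKN1A
CDKN2A
MYC
EGFR
FGFBP1
ILK
ITGB1
MMP9
NOTCH1
PDGFA
PLK1
PTGS2
SOX4
SURV1A
TNFAIP3
VEGFA
WNT5A
ACTB2
ADAM17
BAX
BCL2L1
CASP7
CAV1
CDH1
CTGF
CYR61
DUSP1
EGR1
FOS
GADD45A
HIF1A
IGFBP3
JUNB
KRT13
LAMA3
MKI67
NFKB1
PCNA
RBL2
SERPINE1
SMAD4
SPARC
TGFB1
TIMP1
TP63
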