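N4BP1
FNDC3A
HAND1
IGF1R
OSBPL3
RRM2
STX3
ASH1L
CAPZA2
YWHAH
AFF4
IFI16
COL5A2
GJA1
ALCAM
TXNIP
PLS3
CXCL8
SPARC
FBN1
CDH2
TMEM158
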