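hsa-miR-107	N4BP1
hsa-let-7e-5p	FNDC3A
hsa-let-7e-5p	HAND1
hsa-let-7e-5p	IGF1R
hsa-let-7e-5p	OSBPL3
hsa-let-7e-5p	RRM2
hsa-let-7e-5p	STX3
hsa-miR-107	ASH1L
hsa-miR-107	CAPZA2
hsa-miR-107	YWHAH
hsa-miR-421	AFF4
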