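pathway	from	to
Glycerophospholipid metabolism	LPA	PA
Glycerophospholipid metabolism	PA	CDP-DG
Glycerophospholipid metabolism	CDP-DG	PG
Glycerophospholipid metabolism	PA	PC
Glycerophospholipid metabolism	PC	PE
Glycerophospholipid metabolism	PE	PS
Glycerophospholipid metabolism	LPC	PC
Sphingolipid metabolism	SM	PE-Cer
Sphingolipid metabolism	SM	HexCer
Sphingolipid metabolism	HexCer	ST
Sphingolipid metabolism	HexCer	FMC
Ether lipid metabolism	LPC	PC
Ether lipid metabolism	PC	PE
Fatty acid degradation	FA	CAR
Inositol phosphate metabolism	PI	PA
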