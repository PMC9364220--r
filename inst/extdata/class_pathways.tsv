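pathway	class
Glycerophospholipid metabolism	PA
Glycerophospholipid metabolism	CDP-DG
Glycerophospholipid metabolism	PC
Glycerophospholipid metabolism	PE
Glycerophospholipid metabolism	PG
Glycerophospholipid metabolism	PS
Glycerophospholipid metabolism	LPA
Glycerophospholipid metabolism	LPC
Ether lipid metabolism	LPC
Ether lipid metabolism	PC
Ether lipid metabolism	PE
Sphingolipid metabolism	SM
Sphingolipid metabolism	PE-Cer
Sphingolipid metabolism	ST
Sphingolipid metabolism	HexCer
Sphingolipid metabolism	FMC
Inositol phosphate metabolism	PI
Glycosylphosphatidylinositol anchor biosynthesis	PI
Fatty acid degradation	FA
Fatty acid degradation	CAR
Fatty acid biosynthesis	FA
Glycerolipid metabolism	PA
Glycerolipid metabolism	LPA
Arachidonic acid metabolism	PC
Arachidonic acid metabolism	PE
Linoleic acid metabolism	PC
alpha-Linolenic acid metabolism	PC
alpha-Linolenic acid metabolism	FA
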