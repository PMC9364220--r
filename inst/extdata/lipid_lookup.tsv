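name	formula	note
CDP-DG(40:7)	C52H83N3O15P2	
ST(d18:1/24:1)	C48H91NO11S	
ST(d42:2)	C48H91NO11S	sum-composition alias
HexCer(d34:1)	C40H77NO8	
HexCer(d42:2)	C48H91NO8	
PE-Cer(d36:1)	C38H77N2O6P	
PE-Cer(d38:1)	C40H81N2O6P	
PE-Cer(d38:2)	C40H79N2O6P	
PE-Cer(t40:1)	C42H85N2O7P	
FMC-6(d18:1/22:0(2-OH))	C46H89NO9	provisional: structure not fully characterized
WE(34:1)	C34H66O2	
WE(36:2)	C36H68O2	
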