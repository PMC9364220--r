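name	formula	monoisotopic_mass	adduct	mode	adduct_mz
FA(22:6)	C22H32O2	328.24023	[M-H]-	neg	327.23295
CAR(16:0)	C23H45NO4	399.33486	[M+H]+	pos	400.34214
CAR(16:1)	C23H43NO4	397.31921	[M+H]+	pos	398.32649
PA(38:5)	C41H71O8P	722.48866	[M-H]-	neg	721.48138
PA(38:3)	C41H75O8P	726.51996	[M-H]-	neg	725.51268
PC(34:1)	C42H82NO8P	759.57781	[M+H]+	pos	760.58508
PC(35:3)	C43H80NO8P	769.56216	[M+H]+	pos	770.56943
PC(42:8)	C50H84NO8P	857.59346	[M+H]+	pos	858.60073
PE(36:2)	C41H78NO8P	743.54650	[M-H]-	neg	742.53923
PE(36:4)	C41H74NO8P	739.51520	[M-H]-	neg	738.50793
PE(42:5)	C47H84NO8P	821.59346	[M-H]-	neg	820.58618
PG(43:6)	C49H85O10P	864.58804	[M-H]-	neg	863.58076
PI(34:0)	C43H83O13P	838.55713	[M-H]-	neg	837.54985
PI(38:4)	C47H83O13P	886.55713	[M-H]-	neg	885.54985
PS(41:5)	C47H82NO10P	851.56763	[M-H]-	neg	850.56036
LPA(22:6)	C25H39O7P	482.24334	[M-H]-	neg	481.23606
LPC(O-14:1)	C22H46NO6P	451.30627	[M+H]+	pos	452.31355
SM(d34:1)	C39H79N2O6P	702.56757	[M+H]+	pos	703.57485
SM(d36:1)	C41H83N2O6P	730.59887	[M+H]+	pos	731.60615
PE(O-36:5)	C41H74NO7P	723.52029	[M-H]-	neg	722.51301
PC(O-36:1)	C44H88NO7P	773.62984	[M+H]+	pos	774.63712
PE-Cer(d36:1)	C38H77N2O6P	688.55192	[M-H]-	neg	687.54465
PE-Cer(t40:1)	C42H85N2O7P	760.60944	[M-H]-	neg	759.60216
ST(d18:1/24:1)	C48H91NO11S	889.63128	[M-H]-	neg	888.62401
HexCer(d34:1)	C40H77NO8	699.56492	[M-H]-	neg	698.55764
CDP-DG(40:7)	C52H83N3O15P2	1051.52994	[M-H]-	neg	1050.52267
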