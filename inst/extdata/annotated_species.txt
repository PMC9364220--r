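FA(22:6)
CAR(16:0)
CAR(16:1)
CAR(16:2)
PA(38:5)
PA(38:3)
CDP-DG(40:7)
LPA(22:6)
LPC(O-14:1)
PC(35:3)
PC(42:8)
PC(O-36:1)|PC(P-36:0)
PE(36:2)
PE(36:4)
PE(42:5)
PE(P-42:4)
PE(O-42:6)
PE(O-36:5)|PE(P-36:4)
PE(O-40:4)|PE(P-40:3)
PE(O-40:1)|PE(P-40:0)
PE(O-36:3)|PE(P-36:2)
PE(O-40:2)|PE(P-40:1)
PG(43:6)
PG(O-42:6)
PG(P-42:6)
PS(41:5)
PS(O-36:2)|PS(P-36:1)
PS(O-36:3)|PS(P-36:2)
PE-Cer(t40:1)
PE-Cer(d38:2)|SM(d36:2)
PE-Cer(d38:1)|SM(d36:1)
PE-Cer(d36:1)|SM(d34:1)
ST(d18:1/24:1)
HexCer(d34:1)
FMC-6(d18:1/22:0(2-OH))
PI(34:0)
PI(36:3)
PI(38:4)
PI(41:0)
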