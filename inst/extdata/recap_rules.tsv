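rule_id	smarts	enabled
amide	[$([CX3]=O):1]-[NX3:2]	TRUE
ester	[$([CX3]=O):1]-[OX2;$([OX2]([#6])[#6]):2]	TRUE
amine	[NX3;!$(N~[!#6;!#1]);!$(N-C=[O,N,S]):1]-[CX4:2]	TRUE
urea	[NX3;$(N-C(=O)-N):1]-[$([CX3](=O)(-N)-N):2]	TRUE
ether	[OX2;$([OX2]([#6])[#6]);!$(O-C=O):1]-[#6:2]	TRUE
olefin	[CX3:1]=[CX3:2]	FALSE
quaternary_n	[N+;X4:1]-[C:2]	TRUE
aromatic_n_aliphatic_c	[n:1]-[CX4:2]	TRUE
lactam_n_aliphatic_c	[N;R;$(N-C(=O)):1]-[CX4;!R:2]	TRUE
aromatic_c_aromatic_c	[c:1]-[c:2]	TRUE
sulfonamide	[$([SX4](=O)(=O)):1]-[NX3:2]	TRUE
ext_1	[!#1:1]~[!#1:2]	FALSE
ext_2	[!#1:1]~[!#1:2]	FALSE
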