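name	smarts
nitro	[N+](=O)[O-]
aldehyde	[CX3H1](=O)[#6]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
alkyl_bromide_iodide	[CX4][Br,I]
epoxide	C1OC1
aziridine	C1NC1
azide	N=[N+]=[N-]
diazonium	[N+]#N
isocyanate	N=C=O
isothiocyanate	N=C=S
thiol	[SX2H]
michael_acceptor	[CX3]=[CX3][CX3]=O
hydrazine	[NX3][NX3]
peroxide	[OX2][OX2]
anhydride	C(=O)OC(=O)
sulfonyl_halide	S(=O)(=O)[F,Cl,Br]
nitroso	[NX2]=O
disulfide	[SX2][SX2]
alpha_halo_ketone	[CX3](=O)[CX4][Cl,Br,I]
dicarbonyl_1_2	C(=O)C(=O)
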