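# rulepath functional-group library, version 1.
# Fixed SMARTS library of hetero-atom-containing functional groups used by
# the applicability-domain coverage assessment. Every pattern contains at
# least one hetero atom (N, O, S, P or halogen).
group_id	name	smarts
hydroxyl	Hydroxyl	[OX2H][#6]
carboxylic_acid	Carboxylic acid	[CX3](=O)[OX2H1]
ester	Ester	[CX3](=O)[OX2][#6]
amide	Amide	[CX3](=O)[NX3]
primary_amine	Primary amine	[NX3;H2;!$(NC=O)][#6]
secondary_amine	Secondary amine	[NX3;H1;!$(NC=O)]([#6])[#6]
tertiary_amine	Tertiary amine	[NX3;H0;!$(NC=O);!$(N=O);!$(N~O)]([#6])([#6])[#6]
nitro	Nitro	[NX3+](=O)[O-]
nitrile	Nitrile	[CX2]#[NX1]
ether	Ether	[OD2]([#6])[#6]
thioether	Thioether	[SX2]([#6])[#6]
sulfoxide	Sulfoxide	[SX3](=O)([#6])[#6]
sulfone	Sulfone	[SX4](=O)(=O)([#6])[#6]
sulfonamide	Sulfonamide	[SX4](=O)(=O)[NX3]
aryl_halide	Halide on aromatic carbon	[c][F,Cl,Br,I]
alkyl_halide	Halide on aliphatic carbon	[CX4][F,Cl,Br,I]
phosphate_ester	Phosphate ester	[PX4](=O)[OX2][#6]
ketone	Ketone	[#6][CX3](=O)[#6]
aldehyde	Aldehyde	[CX3H1]=O
carbamate	Carbamate	[NX3][CX3](=O)[OX2]
urea	Urea	[NX3][CX3](=O)[NX3]
azo	Azo	[#6][NX2]=[NX2][#6]
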