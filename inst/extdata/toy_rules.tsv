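# rulepath toy rule library "toy12", version 1.
# Columns: rule_id, name, smirks, example_smiles, example_products.
# example_products lists the product multisets obtained by applying the rule
# to example_smiles: product sets separated by '|', products within a set by
# '.', all as stereo-stripped canonical SMILES, sets and members sorted.
rule_id	name	smirks	example_smiles	example_products
ester_hydrolysis	Ester hydrolysis to acid and alcohol	[C:1](=[O:2])[O:3][C:4]>>[C:1](=[O:2])[O:3].[C:4][OH]	CCOC(C)=O	CC(=O)O.CCO
amide_hydrolysis	Amide hydrolysis to acid and amine	[C:1](=[O:2])[N:3]>>[C:1](=[O:2])[OH].[N:3]	CC(=O)NC	CC(=O)O.CN
aromatic_hydroxylation	Aromatic ring hydroxylation	[cH:1]>>[c:1][OH]	Cc1ccccc1	Cc1ccc(O)cc1|Cc1cccc(O)c1|Cc1ccccc1O
aliphatic_hydroxylation	Terminal methyl hydroxylation	[CH3:1]>>[CH2:1][OH]	CCC	CCCO
nitro_reduction	Nitro group reduction to amine	[NX3+:1](=[O])[O-]>>[NH2+0:1]	O=[N+]([O-])c1ccccc1	Nc1ccccc1
n_dealkylation	N-demethylation releasing formaldehyde	[NX3:1][CH3:2]>>[NX3:1].[CH2:2]=O	CNc1ccccc1	C=O.Nc1ccccc1
o_dealkylation	O-demethylation releasing formaldehyde	[#6:1][O:2][CH3:3]>>[#6:1][O:2].[CH2:3]=O	COc1ccccc1	C=O.Oc1ccccc1
aromatic_dehalogenation	Hydrolytic aromatic dechlorination	[c:1][Cl]>>[c:1][OH]	Clc1ccccc1	Oc1ccccc1
alcohol_oxidation	Primary alcohol oxidation to carboxylic acid	[CX4;H2:1][OH:2]>>[C:1](=[O])[OH:2]	OCc1ccccc1	O=C(O)c1ccccc1
nitrile_hydrolysis	Nitrile hydrolysis to acid and ammonia	[C:1]#[N:2]>>[C:1](=[O])[OH].[NH3:2]	N#Cc1ccccc1	N.O=C(O)c1ccccc1
sulfoxidation	Thioether oxidation to sulfoxide	[#6:1][SX2:2][#6:3]>>[#6:1][S:2](=[O])[#6:3]	CSc1ccccc1	CS(=O)c1ccccc1
decarboxylation	Decarboxylation releasing carbon dioxide	[#6:1][CX3:2](=[O:3])[OX2H1:4]>>[#6:1].[C:2](=[O:3])=[O:4]	CC(=O)O	C.O=C=O
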