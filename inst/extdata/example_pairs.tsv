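name	smiles1	smiles2	logK
keto_enol	CC=O	C=CO	-6.6
pyridone	O=c1cccc[nH]1	Oc1ccccn1	-3.0
acetamide	CC(N)=O	CC(=N)O	-8.0
propanal	CCC=O	CC=CO	-5.5
iodo_excluded	ICC=O	IC=CO	1.0
out_of_range	CC(N)=O	CC(=N)O	12
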