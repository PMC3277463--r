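# Synonym/structure table for the nine-dialect glucose-6-phosphate
# dehydrogenase fixture. The sugar-phosphate structures are real; the
# nicotinamide/deazaflavin cofactor structures are SYNTHETIC STAND-INS:
# distinct small molecules whose redox-pair relations (oxidized/reduced
# differ by one hydride) are chemically consistent, used only as identity
# placeholders for key-level grouping.
id	names	formula	charge	smiles
g6p	glucose 6-phosphate|D-glucose 6-phosphate	C6H11O9P	-2	OC1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
G6P	glucose 6-phosphate	C6H11O9P	-2	OC1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
C00092	alpha-D-glucose 6-phosphate	C6H11O9P	-2	OC1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
C01172	beta-D-glucose 6-phosphate	C6H11O9P	-2	O[C@H]1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
6pgl	6-phospho-D-glucono-1,5-lactone	C6H9O9P	-2	O=C1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
D6PGL	D-glucono-1,5-lactone 6-phosphate	C6H9O9P	-2	O=C1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
C01236	D-glucono-1,5-lactone 6-phosphate	C6H9O9P	-2	O=C1OC(COP(=O)([O-])[O-])C(O)C(O)C1O
nadp	NADP+|nicotinamide adenine dinucleotide phosphate	C7H10N	1	CC[n+]1ccccc1
NADP	NADP+	C7H10N	1	CC[n+]1ccccc1
C00006	NADP+	C7H10N	1	CC[n+]1ccccc1
nadph	NADPH	C7H11N	0	CCN1CC=CC=C1
NADPH	NADPH	C7H11N	0	CCN1CC=CC=C1
C00005	NADPH	C7H11N	0	CCN1CC=CC=C1
NAD	NAD+	C6H8N	1	C[n+]1ccccc1
NADH	NADH	C6H9N	0	CN1CC=CC=C1
f420-2	coenzyme F420-2	C5H7N2	1	C[n+]1ccncc1
f420-2h2	reduced coenzyme F420-2	C5H8N2	0	CN1CC=NC=C1
h	H+|proton	H	1	[H+]
C00080	H+	H	1	[H+]
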