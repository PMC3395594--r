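residue	pocket	wild_type	resno	conservation_score	substitutions	enzyme_activity	allosteric_inhibition
R132	AMP	R	132	0.185	A,E,I	Sustained	Decreased
K104	AMP	K	104	0.384	Q	Sustained	Decreased
T23	AMP	T	23	0.547	V	Lost	Not detected
Y105	AMP	Y	105	0.747	I	Lost	Not detected
K222	G6P	K	222	0.139	A,E,I,Q	Sustained	Decreased
K218	G6P	K	218	0.242	A,E,I,Q	Sustained	Decreased
Y210	G6P	Y	210	0.399	F,I	Sustained	Decreased
Q225	G6P	Q	225	0.605	I,L	Lost	Not detected
E207	G6P	E	207	0.65	I,L	Lost	Not detected
Y203	G6P	Y	203	0.71	F	Lost	Not detected
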