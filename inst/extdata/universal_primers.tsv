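name	sequence	gene	direction
8F	AGAGTTTGATCCTGGCTCAG	16S	forward
1492R	CGTTACCTTGTTACGACTT	16S	reverse
127F	CYGAATGGGRVAACC	23S	forward
2241R	ACCGCCCCAGTHAAACT	23S	reverse
U1	TGGGATACCACCCTGATCGT	16S	reverse
U2	GTTTGGGCTAATCCGCGTTC	16S	forward
U3	CCGTCACACCACGAGAGTTT	23S	reverse
U4	GTCCGCCGCTAGGTTGATTA	23S	forward
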