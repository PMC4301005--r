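gap	fwd	rev
5-1	AATAGACGGGTCTTCCTGCTTATAC	CGATACAACAGCCGACATTTGATTA
5-6	ACCCTAATCGACTGCTTAATCTTGT	CATCTATTGAACTCATTGAACGGGG
6-10	GATGAACCAAAACCTCACCAAGAAT	CGATTGGATCAAGATATTCGCTACG
10-3	GCATCCACAATACGACCCATAAAAT	GAATGTAGGACGAACGGGTAAAATC
3-4	CGGATTACCTCAAAAGGATTGGATG	AAAGAACCATCATGCACAGACAAAT
12-1	GTGCCGTTCTAATGTGTAGCTTATC	AGATGGATAGTAGTCAGGCAAATCC
9-2	GTATATCGGGGAAAGAGTAGGCAAT	GGTGTTTGTGTTGTAAGCTGTATGA
8-4	TTGTTTGATACGTTTGGTACCTTGG	TCTCCAAGTCAGCGTTCGTC
13-11	GACATGGTTGATTGAAAGTGACTGG	AGTGCTCAGCATGGAAGCAA
11-7	TGGTCAATGTAAAACGCAATCTTCA	CCATCATATCCGGGCACCAA
7-15	GCACTGAATAATCCCATTCTCAACC	TGAGGCAACAAGAATCCGCT
4-15	ACATGTTGCTTTCTTTTGCTGA	GGACAACCAGGATACCGCAA
4-13	AACCTGCTGATTATGCGGCT	AGTGCTTGCAAAGTTGGCTC
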