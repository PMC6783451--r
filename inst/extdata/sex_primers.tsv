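pair	name	role	sequence	expected_bp
pair_I	sca64_3724604_F	forward	TGCACCTGTAACTCACTAACCG	113
pair_I	sca64_3724604_R	reverse	CCTTTTCCTGGCCTCTTTACAT	113
pair_II	sca64_3726411_F	forward	GCAGACAAAAAGCCATTCG	143
pair_II	sca64_3726411_R_A	reverse	CTGATGACCTCTGTAACACAATCAT	143
pair_II	sca64_3726411_R_T	reverse	CTGATGTCCTCTGTAACACAATCAT	143
pair_III	sca64_3724591_F	forward	CAGAAATCACCAGTGCACC	142;149
pair_III	sca64_3724591_R	reverse	GGATATTATTAGGAAACCTTTTCCTG	142;149
pair_IV	ND4_F	forward	ACAGACCCGTTGTCAACTCC	268
pair_IV	ND4_R	reverse	TCCCTGCATTTAAACGCTCT	268
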