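id	sequence	length	count_A	count_B	fold_printed
miRN01	TGAGAGAAGGAATTAGATTCA	21	22	18	-0.3
miRN02	CTTGAGGAGGTGTATAGAGGTTA	23	6	8	0.4
miRN03	TTTTACTGCTACTTGTGTTCC	21	9	13	0.5
miRN04	ATACTGAAGATGAAACTAGCT	21	6	6	0
miRN05	TAGTGTTTTTTATGGATCGTCTA	23	12	28	1.2
miRN06	AAAGATGCAGATCATATGTCC	21	17	38	1.2
miRN07	TGGCGAGGATGAATAATGCTAA	22	28	153	2.4
miRN08	TTCGGTTCGGTTCGGTTCGGTTA	23	14	27	0.9
miRN09	TTGGTAGTGGATAAGGGGGCA	21	71	226	1.7
miRN10	TACAGAGTAGTCAAGCATGACC	22	21	26	0.3
miRN11	TTGTCGATGTTTTTTTTACGGTA	23	13	13	0
miRN12	TGGGGTATTGTTGGAGTTTATTA	23	9	7	-0.4
miRN13	TTGACTGCATTAACTTGATCG	21	24	9	-1.4
miRN14	TGACATCCAGATAGAAGCTTT	21	1145	82	-3.8
miRN15	AGACACGGAGAAATCGGGAGATC	23	9	13	0.5
miRN16	ACAGTGGTCATCTGGTGGGCT	21	8	22	1.5
miRN17	AAAGAATCGTTGTTCAAGCTA	21	8	36	2.2
miRN18	TTTGAATTTTTAGAGCATGTCCA	23	12	11	-0.1
miRN19	TTAGTCGAATATGTTTTGGTTTA	23	5	6	0.3
miRN20	TACAAGGAGTCAAGCATGACC	21	14	81	2.5
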