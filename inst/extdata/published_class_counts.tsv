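class	unique_A	total_A	unique_B	total_B
rRNA	18852	307668	16787	281621
snRNA	1116	2188	1907	5497
snoRNA	1668	3297	2209	6236
tRNA	6099	301115	6404	1007667
other	2131218	9067082	1915407	8984342
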