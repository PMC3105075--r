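# Synthetic reference glycoside hydrolase family count profiles.
# These are NOT measured genomes: they are constructed fixtures emulating
# two ecological guilds -- cellulolytic-like profiles dominated by
# GH5/GH6/GH9/GH45/GH48 and oligosaccharide/hemicellulose-like profiles
# dominated by GH1/GH2/GH3/GH13 -- for exercising profile clustering.
sample	GH1	GH2	GH3	GH5	GH6	GH9	GH10	GH11	GH13	GH43	GH45	GH48
synthetic_cellulolytic_A	8	2	4	40	35	28	14	16	5	10	30	26
synthetic_cellulolytic_B	10	3	5	36	30	24	18	20	6	12	26	22
synthetic_oligosaccharide_A	52	38	44	6	1	2	12	8	40	18	0	0
synthetic_oligosaccharide_B	48	42	40	8	2	3	10	6	44	16	1	0
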