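FAM1	1	0	0	2	2	1	62
FAM1	2	0	0	2	2	1	53
FAM1	3	0	0	2	1	0	65
FAM1	4	0	0	2	2	1	35
FAM1	5	9	2	2	2	1	35
FAM1	6	9	2	2	2	1	36
FAM1	7	10	4	2	2	1	35
FAM1	8	10	4	1	1	0	45
FAM1	9	0	0	1	1	0	-9
FAM1	10	0	0	1	1	0	-9
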