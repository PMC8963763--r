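gene	variable	level	M	HM	U
BRD9	stage_group	II	32	5	3
BRD9	stage_group	III-IV	8	20	2
BRD9	tumor_size_group	<5cm	30	11	2
BRD9	tumor_size_group	>=5cm	9	11	3
CTU1	stage_group	II	0	8	31
CTU1	stage_group	III-IV	1	20	9
CTU1	tumor_size_group	<5cm	0	14	29
CTU1	tumor_size_group	>=5cm	1	16	9
DOCK8	stage_group	II	0	25	15
DOCK8	stage_group	III-IV	0	8	22
DOCK8	tumor_size_group	<5cm	0	20	21
DOCK8	tumor_size_group	>=5cm	0	9	16
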