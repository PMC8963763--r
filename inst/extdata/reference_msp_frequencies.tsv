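gene	group	M	HM	U
BRD9	CR	40	0	0
BRD9	TR	0	25	5
CTU1	CR	0	0	40
CTU1	TR	1	27	2
DOCK8	CR	0	31	9
DOCK8	TR	0	1	29
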