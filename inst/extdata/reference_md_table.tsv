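gene	md
KIAA1539	2.4407
DCTPP1	2.3529
STAG3L3	2.3171
CTU1	2.2560
SLC17A7	2.2266
EPB41L1	1.7668
DOCK8	1.7396
PRPF40B	1.6712
HPS1	1.6231
TUBGCP2	1.6421
BRD9	1.6130
RNASEH2A	1.4513
SNX17	1.4315
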