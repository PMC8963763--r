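gene	cpg_density_percent
BRD9	88
CTU1	63
DOCK8	90
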