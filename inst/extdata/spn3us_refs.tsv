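protein_id	known_copies
gp75	1560
gp256	264
gp81	12
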