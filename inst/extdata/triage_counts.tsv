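triage_class	n_regions	of_which_possibly_assembly
no_domain	42	0
nonfunctional	37	15
functional	90	0
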