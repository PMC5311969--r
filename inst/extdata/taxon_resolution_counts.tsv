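rank	n_taxa
genus	26
species	7
family	6
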