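#chromosome	n_species
Chr01	8
Chr02	2
Chr03	5
Chr05	5
Chr08	1
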