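#chromosome	n_genes
Chr01	3500
Chr02	3100
Chr03	2800
Chr04	2600
Chr05	2300
Chr06	2100
Chr07	1900
Chr08	1700
Chr09	1500
Chr10	1300
Chr11	1100
Chr12	900
Chr13	700
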