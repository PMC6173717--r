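#event_id	label	ancestral_chr	derived_chr	ancestral_system	derived_system	scope
e01	root_region_turnover_1	unknown	unknown	XY	XY	interspecific
e02	root_region_turnover_2	unknown	unknown	XY	XY	interspecific
e03	R_iberica_lineage	Chr01	Chr03	XY	XY	interspecific
e04	R_dalmatina_lineage	Chr01	Chr05	XY	XY	interspecific
e05	R_kukunoris_lineage	Chr01	Chr05	XY	XY	interspecific
e06	R_blairi_lineage	Chr01	Chr05	XY	XY	interspecific
e07	R_pipiens_west_lineage	Chr01	Chr05	XY	XY	interspecific
e08	G_rugosa_lineage	unknown	Chr08	XY	XY	interspecific
e09	R_japonica_east	Chr01	Chr03	XY	XY	intraspecific
e10	R_pipiens_east	Chr05	Chr02	XY	XY	intraspecific
e11	P_porosus_okayama	Chr03	Chr05	XY	XY	intraspecific
e12	G_rugosa_ZW_race_1	Chr08	Chr08	XY	ZW	homologous
e13	G_rugosa_ZW_race_2	Chr08	Chr08	XY	ZW	homologous
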