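#species	Chr01	Chr02	Chr03	Chr05	Chr08
Rana_temporaria	0.5	0.5	0	0	0
Rana_arvalis	1	0	0	0	0
Rana_italica	1	0	0	0	0
Rana_japonica	0.5	0	0.5	0	0
Rana_montezumae	1	0	0	0	0
Rana_amurensis	1	0	0	0	0
Rana_dybowskii	1	0	0	0	0
Rana_sylvatica	1	0	0	0	0
Rana_pipiens	0	0.5	0	0.5	0
Rana_iberica	0	0	1	0	0
Rana_dalmatina	0	0	0	1	0
Rana_kukunoris	0	0	0	1	0
Rana_blairi	0	0	0	1	0
Glandirana_rugosa	0	0	0	0	1
Pelophylax_perezi	0	0	1	0	0
Pelophylax_lessonae	0	0	1	0	0
Pelophylax_porosus	0	0	0.5	0.5	0
Rana_berlandieri	0.2	0.2	0.2	0.2	0.2
Rana_sphenocephala	0.2	0.2	0.2	0.2	0.2
Rana_chiricahuensis	0.2	0.2	0.2	0.2	0.2
Rana_yavapaiensis	0.2	0.2	0.2	0.2	0.2
Rana_tarahumarae	0.2	0.2	0.2	0.2	0.2
Rana_latastei	0.2	0.2	0.2	0.2	0.2
Rana_macrocnemis	0.2	0.2	0.2	0.2	0.2
Rana_chensinensis	0.2	0.2	0.2	0.2	0.2
Rana_ornativentris	0.2	0.2	0.2	0.2	0.2
Rana_uenoi	0.2	0.2	0.2	0.2	0.2
Pelophylax_saharicus	0.2	0.2	0.2	0.2	0.2
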