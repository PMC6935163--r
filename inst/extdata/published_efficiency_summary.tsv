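trait	pedigree	r_ihg	r_iha	e17	e14
branch_cluster_frequency	documented	0.50	0.77	1.28	1.05
stem_straightness	documented	0.47	0.73	0.98	0.81
internal_checking	documented	0.51	0.71	0.92	0.75
external_resin_bleeding	documented	0.54	0.65	0.91	0.75
branch_cluster_frequency	corrected	0.70	0.78	2.15	1.77
stem_straightness	corrected	0.55	0.72	1.51	1.25
internal_checking	corrected	0.59	0.70	1.37	1.13
external_resin_bleeding	corrected	0.57	0.64	1.02	0.84
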