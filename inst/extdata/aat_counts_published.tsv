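taxon	set	life_history	host	apc	aaap	aaap_extra	total
Daktulosphaira_vitifoliae	ingroup	galling	Vitis	11	12	0	23
Phylloxera_caryaecaulis	ingroup	galling	Carya_glabra	10	16	0	26
Phylloxera_caryaemagna	ingroup	galling	Carya_cordiformis	10	15	0	25
Phylloxera_subelliptica	ingroup	galling	Carya_ovata	10	12	0	22
Phylloxera_caryaevenae	ingroup	galling	Carya_glabra	8	12	0	20
Phylloxera_foveola	ingroup	galling	Carya_glabra	7	14	0	21
Phylloxera_foveata	ingroup	galling	Carya_glabra	13	17	0	30
Phylloxera_caryaefallax	ingroup	galling	Carya_ovata	9	14	0	23
Phylloxera_quercus	ingroup	free_living	Quercus	19	24	0	43
Acyrthosiphon_pisum	ingroup	free_living	Fabaceae	18	21	0	39
Myzus_persicae	ingroup	free_living	diverse	16	20	0	36
Pemphigus_obesinymphae	ingroup	galling	Populus	11	14	4	25
Pemphigus_populicaulis	ingroup	galling	Populus	12	18	0	30
Tamalia_coweni	ingroup	galling	Arctostaphylos	12	16	5	28
Tamalia_inquilinus	ingroup	inquiline	Arctostaphylos	10	17	0	27
Planococcus_citri	outgroup_sternorrhyncha	free_living	diverse	10	28	0	38
Bemisia_tabaci	outgroup_sternorrhyncha	free_living	diverse	12	24	0	36
Bactericera_cockerelli	outgroup_sternorrhyncha	free_living	diverse	10	25	0	35
Drosophila_melanogaster	outgroup_nonherbivore	free_living	none	10	15	0	25
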