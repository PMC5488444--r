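(Drosophila_melanogaster:1,((Bactericera_cockerelli:1,(Bemisia_tabaci:1,Planococcus_citri:1):1):1,(((Acyrthosiphon_pisum:1,Myzus_persicae:1):1,((Pemphigus_obesinymphae:1,Pemphigus_populicaulis:1):1,(Tamalia_coweni:1,Tamalia_inquilinus:1):1):1):1,(Daktulosphaira_vitifoliae:1,(((Phylloxera_caryaecaulis:1,Phylloxera_caryaemagna:1):1,Phylloxera_subelliptica:1):1,((Phylloxera_caryaevenae:1,((Phylloxera_foveola:1,Phylloxera_foveata:1):1,Phylloxera_caryaefallax:1):1):1,Phylloxera_quercus:1):1):1):1):1):1);
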