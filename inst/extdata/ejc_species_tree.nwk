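((Cryptococcus_neoformans,Ustilago_maydis),(Schizosaccharomyces_pombe,((Neurospora_crassa,Aspergillus_nidulans),((Yarrowia_lipolytica,(Candida_hispaniensis,(Geotrichum_candidum,(Blastobotrys_adeninivorans,Sugiyamaella_lignohabitans)))),(((Candida_albicans,(Candida_tropicalis,(Candida_parapsilosis,(Debaryomyces_hansenii,(Meyerozyma_guilliermondii,(Scheffersomyces_stipitis,Clavispora_lusitaniae)))))),(Komagataella_phaffii,(Ogataea_polymorpha,(Pichia_membranifaciens,Brettanomyces_bruxellensis)))),((Cyberlindnera_fabianii,Wickerhamomyces_ciferrii),(Saccharomyces_cerevisiae,(Candida_glabrata,(Kazachstania_africana,(Naumovozyma_castellii,(Zygosaccharomyces_rouxii,(Torulaspora_delbrueckii,(Kluyveromyces_lactis,(Lachancea_thermotolerans,Eremothecium_gossypii))))))))))))));
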