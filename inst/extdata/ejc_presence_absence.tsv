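# Curated presence/absence calls for exon junction complex core components
# (MAGO, Y14) and peripheral factors (UPF3, PYM, ALY_REF, IBP160) across 32
# Ascomycota and Basidiomycota species, encoded from a published comparative
# homology survey. MAGO/Y14/PYM calls follow the survey species by species;
# UPF3, ALY_REF and IBP160 calls summarize its clade-level statements
# (UPF3 near-universal; Aly/REF absent from Saccharomycetaceae and part of
# the CTG clade; IBP160 absent from Saccharomycetaceae, present in most CTG
# species). family: CTG = CUG-Ser clade; outgroup rows reuse their subphylum
# or phylum as the family label.
species	group	family	MAGO	Y14	UPF3	PYM	ALY_REF	IBP160
Cryptococcus_neoformans	Basidiomycota	Basidiomycota	+	+	+	+	+	+
Ustilago_maydis	Basidiomycota	Basidiomycota	+	+	+	+	+	+
Schizosaccharomyces_pombe	Taphrinomycotina	Taphrinomycotina	+	+	+	+	+	+
Neurospora_crassa	Pezizomycotina	Pezizomycotina	+	+	+	+	+	+
Aspergillus_nidulans	Pezizomycotina	Pezizomycotina	+	+	+	+	+	+
Yarrowia_lipolytica	Saccharomycotina	Yarrowiaceae	+	+	+	+	+	+
Candida_hispaniensis	Saccharomycotina	Yarrowiaceae	+	+	+	+	+	+
Geotrichum_candidum	Saccharomycotina	Yarrowiaceae	+	+	+	+	+	+
Blastobotrys_adeninivorans	Saccharomycotina	Yarrowiaceae	+	+	+	+	+	+
Sugiyamaella_lignohabitans	Saccharomycotina	Yarrowiaceae	+	+	+	+	+	+
Cyberlindnera_fabianii	Saccharomycotina	Phaffomycetaceae	+	+	+	+	+	+
Wickerhamomyces_ciferrii	Saccharomycotina	Phaffomycetaceae	+	+	+	+	+	+
Komagataella_phaffii	Saccharomycotina	Pichiaceae	-	-	+	-	+	+
Ogataea_polymorpha	Saccharomycotina	Pichiaceae	-	-	+	-	+	+
Pichia_membranifaciens	Saccharomycotina	Pichiaceae	-	-	+	-	+	+
Brettanomyces_bruxellensis	Saccharomycotina	Pichiaceae	-	-	+	-	+	+
Candida_albicans	Saccharomycotina	CTG	-	-	+	-	-	+
Candida_tropicalis	Saccharomycotina	CTG	-	-	+	-	-	+
Candida_parapsilosis	Saccharomycotina	CTG	-	-	+	-	-	+
Debaryomyces_hansenii	Saccharomycotina	CTG	-	-	+	-	+	+
Meyerozyma_guilliermondii	Saccharomycotina	CTG	-	-	+	-	+	-
Scheffersomyces_stipitis	Saccharomycotina	CTG	-	-	+	-	+	+
Clavispora_lusitaniae	Saccharomycotina	CTG	-	-	+	-	+	+
Saccharomyces_cerevisiae	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Candida_glabrata	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Kazachstania_africana	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Naumovozyma_castellii	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Zygosaccharomyces_rouxii	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Torulaspora_delbrueckii	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Kluyveromyces_lactis	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Lachancea_thermotolerans	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
Eremothecium_gossypii	Saccharomycotina	Saccharomycetaceae	-	-	+	-	-	-
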