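taxon	stratum
Chlamydomonas_reinhardtii	Chlamydomonas
Chlamydomonas_incerta	Chlamydomonas
Gonium_pectorale	volvocine
Volvox_carteri	volvocine
Tetrabaena_socialis	volvocine
Dunaliella_salina	Chlamydomonadales
Monoraphidium_neglectum	Chlorophyceae
Scenedesmus_obliquus	Chlorophyceae
Ostreococcus_tauri	Chlorophyta
Micromonas_pusilla	Chlorophyta
Arabidopsis_thaliana	Viridiplantae
Physcomitrella_patens	Viridiplantae
Homo_sapiens	Eukaryota
Saccharomyces_cerevisiae	Eukaryota
Dictyostelium_discoideum	Eukaryota
Escherichia_coli	cellular organisms
Bacillus_subtilis	cellular organisms
Sulfolobus_solfataricus	cellular organisms
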