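species_id	taxon_group	enhancer	prr	cpg_island
Ornithorhynchus_anatinus	Monotremata	X	X	X
Monodelphis_domestica	Marsupialia	X	X	X
Macropus_eugenii	Marsupialia	/	/	X
Sarcophilus_harrisii	Marsupialia	/	/	X
Choloepus_hoffmanni	Xenarthra	X	/	/
Dasypus_novemcinctus	Xenarthra	X	X	Yes
Mylodon_darwinii	Xenarthra	Yes	/	/
Chrysochloris_asiatica	Afrotheria	Yes	Yes	X
Dugong_dugon	Afrotheria	Yes	Yes	/
Echinops_telfairi	Afrotheria	Yes	Yes	Yes
Elephantulus_edwardii	Afrotheria	Yes	Yes	X
Elephas_maximus	Afrotheria	Yes	Yes	Yes
Hydrodamalis_gigas	Afrotheria	Yes	/	/
Loxodonta_africana	Afrotheria	Yes	Yes	Yes
Mammuthus_primigenius	Afrotheria	Yes	Yes	/
Orycteropus_afer	Afrotheria	Yes	Yes	X
Procavia_capensis	Afrotheria	X	Yes	Yes
Trichechus_manatus_latirostris	Afrotheria	Yes	Yes	Yes
Acinonyx_jubatus	Laurasiatheria	Yes	Yes	Yes
Ailuropoda_melanoleuca	Laurasiatheria	Yes	Yes	Yes
Balaena_mysticetus	Laurasiatheria	Yes	Yes	Yes
Balaenoptera_acutorostrata	Laurasiatheria	Yes	Yes	Yes
Balaenoptera_bonaerensis	Laurasiatheria	Yes	Yes	Yes
Balaenoptera_physalus	Laurasiatheria	Yes	Yes	Yes
Bison_bison	Laurasiatheria	Yes	Yes	Yes
Bos_grunniens	Laurasiatheria	Yes	Yes	Yes
Bos_indicus	Laurasiatheria	/	Yes	/
Bos_taurus	Laurasiatheria	Yes	Yes	Yes
Bubalus_bubalis	Laurasiatheria	Yes	Yes	Yes
Camelus_dromedarius	Laurasiatheria	Yes	Yes	Yes
Camelus_ferus	Laurasiatheria	Yes	Yes	Yes
Canis_lupus_familiaris	Laurasiatheria	Yes	X	/
Capra_aegagrus	Laurasiatheria	Yes	Yes	Yes
Capra_hircus	Laurasiatheria	Yes	Yes	/
Capreolus_capreolus	Laurasiatheria	Yes	Yes	Yes
Ceratotherium_simum	Laurasiatheria	Yes	Yes	Yes
Coelodonta_antiquitatis	Laurasiatheria	Yes	Yes	Yes
Condylura_cristata	Laurasiatheria	Yes	X	X
Dicerorhinus_sumatrensis	Laurasiatheria	Yes	Yes	Yes
Diceros_bicornis	Laurasiatheria	Yes	Yes	Yes
Eidolon_helvum	Laurasiatheria	Yes	Yes	/
Eptesicus_fuscus	Laurasiatheria	Yes	X	Yes
Equus_asinus	Laurasiatheria	Yes	Yes	Yes
Equus_caballus	Laurasiatheria	Yes	Yes	/
Equus_przewalskii	Laurasiatheria	Yes	Yes	Yes
Erinaceus_europaeus	Laurasiatheria	/	/	X
Felis_catus	Laurasiatheria	Yes	Yes	Yes
Giraffa_camelopardalis	Laurasiatheria	Yes	Yes	X
Hipposideros_armiger	Laurasiatheria	Yes	Yes	Yes
Leptonychotes_weddellii	Laurasiatheria	Yes	Yes	Yes
Lipotes_vexillifer	Laurasiatheria	Yes	Yes	Yes
Lycaon_pictus	Laurasiatheria	Yes	X	/
Manis_javanica	Laurasiatheria	X	X	X
Manis_pentadactyla	Laurasiatheria	X	X	X
Megaderma_lyra	Laurasiatheria	Yes	/	/
Miniopterus_natalensis	Laurasiatheria	Yes	X	Yes
Mustela_putorius_furo	Laurasiatheria	Yes	Yes	Yes
Myotis_brandtii	Laurasiatheria	Yes	X	Yes
Myotis_davidii	Laurasiatheria	Yes	X	Yes
Myotis_lucifugus	Laurasiatheria	Yes	X	Yes
Odobenus_rosmarus	Laurasiatheria	Yes	Yes	Yes
Okapia_johnstoni	Laurasiatheria	Yes	Yes	Yes
Orcinus_orca	Laurasiatheria	X	X	X
Ovis_aries	Laurasiatheria	Yes	Yes	Yes
Panthera_pardus	Laurasiatheria	Yes	Yes	Yes
Panthera_tigris_altaica	Laurasiatheria	Yes	Yes	Yes
Panthera_uncia	Laurasiatheria	Yes	Yes	/
Pantholops_hodgsonii	Laurasiatheria	Yes	Yes	Yes
Physeter_macrocephalus	Laurasiatheria	X	Yes	Yes
Pteropus_alecto	Laurasiatheria	Yes	Yes	Yes
Pteropus_vampyrus	Laurasiatheria	Yes	Yes	Yes
Rhinoceros_unicornis	Laurasiatheria	Yes	Yes	Yes
Rhinolophus_ferrumequinum	Laurasiatheria	Yes	Yes	Yes
Rhinolophus_sinicus	Laurasiatheria	Yes	Yes	Yes
Rousettus_aegyptiacus	Laurasiatheria	Yes	Yes	Yes
Sorex_araneus	Laurasiatheria	Yes	X	Yes
Sus_cebrifrons	Laurasiatheria	Yes	/	/
Sus_scrofa	Laurasiatheria	Yes	X	X
Sus_verrucosus	Laurasiatheria	Yes	/	/
Tapirus_indicus	Laurasiatheria	Yes	/	Yes
Tursiops_truncatus	Laurasiatheria	X	X	X
Ursus_maritimus	Laurasiatheria	Yes	Yes	/
Vicugna_pacos	Laurasiatheria	Yes	Yes	Yes
Aotus_nancymaae	Euarchontoglires	Yes	Yes	Yes
Apodemus_sylvaticus	Euarchontoglires	Yes	/	X
Callithrix_jacchus	Euarchontoglires	Yes	Yes	Yes
Cavia_aperea	Euarchontoglires	/	/	/
Cavia_porcellus	Euarchontoglires	Yes	Yes	Yes
Cebus_capuchinis	Euarchontoglires	Yes	Yes	Yes
Cercocebus_atys	Euarchontoglires	Yes	Yes	Yes
Chinchilla_lanigera	Euarchontoglires	Yes	Yes	Yes
Chlorocebus_sabaeus	Euarchontoglires	Yes	Yes	Yes
Colobus_angolensis	Euarchontoglires	Yes	Yes	Yes
Cricetulus_griseus	Euarchontoglires	Yes	Yes	X
Daubentonia_madagascariensis	Euarchontoglires	Yes	Yes	/
Dipodomys_ordii	Euarchontoglires	Yes	X	Yes
Ellobius_lutescens	Euarchontoglires	Yes	X	Yes
Ellobius_talpinus	Euarchontoglires	Yes	X	Yes
Eulemur_flavifrons	Euarchontoglires	Yes	Yes	Yes
Eulemur_macaco	Euarchontoglires	Yes	Yes	Yes
Fukomys_damarensis	Euarchontoglires	Yes	Yes	Yes
Galeopterus_variegatus	Euarchontoglires	Yes	Yes	/
Gorilla_gorilla_gorilla	Euarchontoglires	Yes	Yes	Yes
Heterocephalus_glaber	Euarchontoglires	Yes	Yes	Yes
Homo_sapiens	Euarchontoglires	Yes	Yes	Yes
Jaculus_jaculus	Euarchontoglires	Yes	Yes	Yes
Macaca_fascicularis	Euarchontoglires	Yes	Yes	Yes
Macaca_mulatta	Euarchontoglires	Yes	Yes	Yes
Macaca_nemestrina	Euarchontoglires	Yes	Yes	Yes
Mandrillus_leucophaeus	Euarchontoglires	Yes	Yes	Yes
Marmota_marmota	Euarchontoglires	Yes	Yes	Yes
Mesocricetus_auratus	Euarchontoglires	Yes	X	Yes
Microcebus_murinus	Euarchontoglires	Yes	Yes	Yes
Microtus_agrestis	Euarchontoglires	Yes	X	Yes
Microtus_ochrogaster	Euarchontoglires	Yes	X	X
Mus_musculus	Euarchontoglires	Yes	X	X
Mus_spretus	Euarchontoglires	Yes	X	X
Myodes_glareolus	Euarchontoglires	Yes	/	/
Nannospalax_galili	Euarchontoglires	Yes	Yes	X
Nasalis_larvatus	Euarchontoglires	Yes	Yes	Yes
Neotoma_lepida	Euarchontoglires	/	/	X
Nomascus_leucogenys	Euarchontoglires	Yes	Yes	Yes
Ochotona_princeps	Euarchontoglires	Yes	X	X
Octodon_degus	Euarchontoglires	Yes	Yes	Yes
Oryctolagus_cuniculus	Euarchontoglires	Yes	Yes	Yes
Otolemur_garnettii	Euarchontoglires	Yes	Yes	X
Pan_paniscus	Euarchontoglires	Yes	Yes	Yes
Pan_troglodytes	Euarchontoglires	Yes	Yes	/
Papio_anubis	Euarchontoglires	Yes	Yes	Yes
Peromyscus_maniculatus	Euarchontoglires	Yes	X	X
Pongo_abelii	Euarchontoglires	Yes	Yes	Yes
Propithecus_coquereli	Euarchontoglires	Yes	Yes	Yes
Rattus_norvegicus	Euarchontoglires	Yes	X	X
Rhinopithecus_bieti	Euarchontoglires	Yes	Yes	Yes
Rhinopithecus_roxellana	Euarchontoglires	Yes	Yes	Yes
Saimiri_boliviensis	Euarchontoglires	Yes	Yes	Yes
Spermophilus_tridecemlineatus	Euarchontoglires	Yes	Yes	Yes
Tarsius_syrichta	Euarchontoglires	Yes	Yes	/
Tupaia_belangeri_chinensis	Euarchontoglires	Yes	Yes	Yes
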