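species_id	taxon_group	ucp1_status
Ornithorhynchus_anatinus	Monotremata	intact
Monodelphis_domestica	Marsupialia	intact
Macropus_eugenii	Marsupialia	intact
Sarcophilus_harrisii	Marsupialia	intact
Choloepus_hoffmanni	Xenarthra	pseudogene
Dasypus_novemcinctus	Xenarthra	pseudogene
Mylodon_darwinii	Xenarthra	pseudogene
Chrysochloris_asiatica	Afrotheria	intact
Dugong_dugon	Afrotheria	pseudogene
Echinops_telfairi	Afrotheria	intact
Elephantulus_edwardii	Afrotheria	intact
Elephas_maximus	Afrotheria	pseudogene
Hydrodamalis_gigas	Afrotheria	pseudogene
Loxodonta_africana	Afrotheria	pseudogene
Mammuthus_primigenius	Afrotheria	pseudogene
Orycteropus_afer	Afrotheria	intact
Procavia_capensis	Afrotheria	pseudogene
Trichechus_manatus_latirostris	Afrotheria	pseudogene
Acinonyx_jubatus	Laurasiatheria	intact
Ailuropoda_melanoleuca	Laurasiatheria	intact
Balaena_mysticetus	Laurasiatheria	pseudogene
Balaenoptera_acutorostrata	Laurasiatheria	pseudogene
Balaenoptera_bonaerensis	Laurasiatheria	pseudogene
Balaenoptera_physalus	Laurasiatheria	pseudogene
Bison_bison	Laurasiatheria	intact
Bos_grunniens	Laurasiatheria	intact
Bos_indicus	Laurasiatheria	intact
Bos_taurus	Laurasiatheria	intact
Bubalus_bubalis	Laurasiatheria	intact
Camelus_dromedarius	Laurasiatheria	intact
Camelus_ferus	Laurasiatheria	intact
Canis_lupus_familiaris	Laurasiatheria	intact
Capra_aegagrus	Laurasiatheria	intact
Capra_hircus	Laurasiatheria	intact
Capreolus_capreolus	Laurasiatheria	intact
Ceratotherium_simum	Laurasiatheria	intact
Coelodonta_antiquitatis	Laurasiatheria	intact
Condylura_cristata	Laurasiatheria	intact
Dicerorhinus_sumatrensis	Laurasiatheria	intact
Diceros_bicornis	Laurasiatheria	intact
Eidolon_helvum	Laurasiatheria	intact
Eptesicus_fuscus	Laurasiatheria	intact
Equus_asinus	Laurasiatheria	pseudogene
Equus_caballus	Laurasiatheria	pseudogene
Equus_przewalskii	Laurasiatheria	pseudogene
Erinaceus_europaeus	Laurasiatheria	intact
Felis_catus	Laurasiatheria	intact
Giraffa_camelopardalis	Laurasiatheria	intact
Hipposideros_armiger	Laurasiatheria	intact
Leptonychotes_weddellii	Laurasiatheria	intact
Lipotes_vexillifer	Laurasiatheria	pseudogene
Lycaon_pictus	Laurasiatheria	intact
Manis_javanica	Laurasiatheria	pseudogene
Manis_pentadactyla	Laurasiatheria	pseudogene
Megaderma_lyra	Laurasiatheria	intact
Miniopterus_natalensis	Laurasiatheria	intact
Mustela_putorius_furo	Laurasiatheria	intact
Myotis_brandtii	Laurasiatheria	intact
Myotis_davidii	Laurasiatheria	intact
Myotis_lucifugus	Laurasiatheria	intact
Odobenus_rosmarus	Laurasiatheria	intact
Okapia_johnstoni	Laurasiatheria	intact
Orcinus_orca	Laurasiatheria	pseudogene
Ovis_aries	Laurasiatheria	intact
Panthera_pardus	Laurasiatheria	intact
Panthera_tigris_altaica	Laurasiatheria	intact
Panthera_uncia	Laurasiatheria	intact
Pantholops_hodgsonii	Laurasiatheria	intact
Physeter_macrocephalus	Laurasiatheria	pseudogene
Pteropus_alecto	Laurasiatheria	intact
Pteropus_vampyrus	Laurasiatheria	intact
Rhinoceros_unicornis	Laurasiatheria	intact
Rhinolophus_ferrumequinum	Laurasiatheria	intact
Rhinolophus_sinicus	Laurasiatheria	intact
Rousettus_aegyptiacus	Laurasiatheria	intact
Sorex_araneus	Laurasiatheria	intact
Sus_cebrifrons	Laurasiatheria	pseudogene
Sus_scrofa	Laurasiatheria	pseudogene
Sus_verrucosus	Laurasiatheria	pseudogene
Tapirus_indicus	Laurasiatheria	intact
Tursiops_truncatus	Laurasiatheria	pseudogene
Ursus_maritimus	Laurasiatheria	intact
Vicugna_pacos	Laurasiatheria	intact
Aotus_nancymaae	Euarchontoglires	intact
Apodemus_sylvaticus	Euarchontoglires	intact
Callithrix_jacchus	Euarchontoglires	intact
Cavia_aperea	Euarchontoglires	intact
Cavia_porcellus	Euarchontoglires	intact
Cebus_capuchinis	Euarchontoglires	intact
Cercocebus_atys	Euarchontoglires	intact
Chinchilla_lanigera	Euarchontoglires	intact
Chlorocebus_sabaeus	Euarchontoglires	intact
Colobus_angolensis	Euarchontoglires	intact
Cricetulus_griseus	Euarchontoglires	intact
Daubentonia_madagascariensis	Euarchontoglires	intact
Dipodomys_ordii	Euarchontoglires	intact
Ellobius_lutescens	Euarchontoglires	intact
Ellobius_talpinus	Euarchontoglires	intact
Eulemur_flavifrons	Euarchontoglires	intact
Eulemur_macaco	Euarchontoglires	intact
Fukomys_damarensis	Euarchontoglires	intact
Galeopterus_variegatus	Euarchontoglires	intact
Gorilla_gorilla_gorilla	Euarchontoglires	intact
Heterocephalus_glaber	Euarchontoglires	intact
Homo_sapiens	Euarchontoglires	intact
Jaculus_jaculus	Euarchontoglires	intact
Macaca_fascicularis	Euarchontoglires	intact
Macaca_mulatta	Euarchontoglires	intact
Macaca_nemestrina	Euarchontoglires	intact
Mandrillus_leucophaeus	Euarchontoglires	intact
Marmota_marmota	Euarchontoglires	intact
Mesocricetus_auratus	Euarchontoglires	intact
Microcebus_murinus	Euarchontoglires	intact
Microtus_agrestis	Euarchontoglires	intact
Microtus_ochrogaster	Euarchontoglires	intact
Mus_musculus	Euarchontoglires	intact
Mus_spretus	Euarchontoglires	intact
Myodes_glareolus	Euarchontoglires	intact
Nannospalax_galili	Euarchontoglires	intact
Nasalis_larvatus	Euarchontoglires	intact
Neotoma_lepida	Euarchontoglires	intact
Nomascus_leucogenys	Euarchontoglires	intact
Ochotona_princeps	Euarchontoglires	intact
Octodon_degus	Euarchontoglires	intact
Oryctolagus_cuniculus	Euarchontoglires	intact
Otolemur_garnettii	Euarchontoglires	intact
Pan_paniscus	Euarchontoglires	intact
Pan_troglodytes	Euarchontoglires	intact
Papio_anubis	Euarchontoglires	intact
Peromyscus_maniculatus	Euarchontoglires	intact
Pongo_abelii	Euarchontoglires	intact
Propithecus_coquereli	Euarchontoglires	intact
Rattus_norvegicus	Euarchontoglires	intact
Rhinopithecus_bieti	Euarchontoglires	intact
Rhinopithecus_roxellana	Euarchontoglires	intact
Saimiri_boliviensis	Euarchontoglires	intact
Spermophilus_tridecemlineatus	Euarchontoglires	intact
Tarsius_syrichta	Euarchontoglires	intact
Tupaia_belangeri_chinensis	Euarchontoglires	intact
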