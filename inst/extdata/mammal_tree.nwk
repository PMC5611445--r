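(Ornithorhynchus_anatinus,((Monodelphis_domestica,(Macropus_eugenii,Sarcophilus_harrisii)),(((Dasypus_novemcinctus,(Choloepus_hoffmanni,Mylodon_darwinii)),((Orycteropus_afer,(Elephantulus_edwardii,(Chrysochloris_asiatica,Echinops_telfairi))),(Procavia_capensis,((Loxodonta_africana,(Elephas_maximus,Mammuthus_primigenius)),(Trichechus_manatus_latirostris,(Dugong_dugon,Hydrodamalis_gigas)))))),(((Erinaceus_europaeus,(Sorex_araneus,Condylura_cristata)),((((((Pteropus_alecto,Pteropus_vampyrus),Rousettus_aegyptiacus),Eidolon_helvum),(((Rhinolophus_ferrumequinum,Rhinolophus_sinicus),Hipposideros_armiger),Megaderma_lyra)),((((Myotis_brandtii,Myotis_davidii),Myotis_lucifugus),Eptesicus_fuscus),Miniopterus_natalensis)),(((((Equus_caballus,Equus_przewalskii),Equus_asinus),(Tapirus_indicus,((Ceratotherium_simum,Diceros_bicornis),((Dicerorhinus_sumatrensis,Coelodonta_antiquitatis),Rhinoceros_unicornis)))),((((Felis_catus,Acinonyx_jubatus),(Panthera_pardus,(Panthera_tigris_altaica,Panthera_uncia))),((Canis_lupus_familiaris,Lycaon_pictus),((Ursus_maritimus,Ailuropoda_melanoleuca),(Mustela_putorius_furo,(Odobenus_rosmarus,Leptonychotes_weddellii))))),(Manis_javanica,Manis_pentadactyla))),(((Camelus_dromedarius,Camelus_ferus),Vicugna_pacos),((Sus_scrofa,(Sus_cebrifrons,Sus_verrucosus)),(((Giraffa_camelopardalis,Okapia_johnstoni),(Capreolus_capreolus,((((Bos_taurus,Bos_indicus),(Bos_grunniens,Bison_bison)),Bubalus_bubalis),((Capra_hircus,Capra_aegagrus),(Ovis_aries,Pantholops_hodgsonii))))),((Balaena_mysticetus,(Balaenoptera_physalus,(Balaenoptera_acutorostrata,Balaenoptera_bonaerensis))),(Physeter_macrocephalus,(Lipotes_vexillifer,(Orcinus_orca,Tursiops_truncatus)Delphinidae))))))))),(((Oryctolagus_cuniculus,Ochotona_princeps),((Marmota_marmota,Spermophilus_tridecemlineatus),((Dipodomys_ordii,(Jaculus_jaculus,(Nannospalax_galili,(((Peromyscus_maniculatus,Neotoma_lepida),((Cricetulus_griseus,Mesocricetus_auratus),(Myodes_glareolus,((Microtus_agrestis,Microtus_ochrogaster),(Ellobius_lutescens,Ellobius_talpinus))))),(((Mus_musculus,Mus_spretus),Apodemus_sylvaticus),Rattus_norvegicus))))),(((Cavia_aperea,Cavia_porcellus),(Chinchilla_lanigera,Octodon_degus)),(Fukomys_damarensis,Heterocephalus_glaber))))),(Tupaia_belangeri_chinensis,(Galeopterus_variegatus,((Otolemur_garnettii,(Daubentonia_madagascariensis,(Microcebus_murinus,(Propithecus_coquereli,(Eulemur_flavifrons,Eulemur_macaco))))),(Tarsius_syrichta,((((Cebus_capuchinis,Saimiri_boliviensis),Callithrix_jacchus),Aotus_nancymaae),(((((Macaca_fascicularis,Macaca_mulatta),Macaca_nemestrina),((Papio_anubis,(Mandrillus_leucophaeus,Cercocebus_atys)),Chlorocebus_sabaeus)),(Colobus_angolensis,(Nasalis_larvatus,(Rhinopithecus_bieti,Rhinopithecus_roxellana)))),(Nomascus_leucogenys,(Pongo_abelii,(Gorilla_gorilla_gorilla,(Homo_sapiens,(Pan_paniscus,Pan_troglodytes))))))))))))))Eutheria))Mammalia;
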