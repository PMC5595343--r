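class,family,taxon,level,N,O,W
Teleost,Bothidae,Bothidae,family,1,1,142.01
Teleost,Carangidae,Trachurus sp.,species,10,2,422.50
Teleost,Centracanthidae,Spicara maena,species,2,1,
Teleost,Centriscidae,Macroramphosus sp.,species,176,1,
Teleost,Cepolidae,Cepola macrophthalma,species,256,2,7007.84
Teleost,Citharidae,Citharus linguatula,species,2,2,74.24
Teleost,Clupeidae,Sardina pilchardus,species,17,3,1188.95
Teleost,Congridae,Conger conger,species,215,8,50603.24
Teleost,Engraulidae,Engraulis encrasicoliis,species,1,1,176.45
Teleost,Gadidae,Gadidae,family,24,7,249.04
Teleost,Gadidae,Gadiculus argenteus,species,9,2,47.93
Teleost,Gadidae,Micromesistius poutassou,species,4,2,15.05
Teleost,Gadidae,Trisopterus sp.,species,10,2,186.06
Teleost,Gadidae,unidentified Gadidae,species,1,1,
Teleost,Gobiidae,Gobiidae,family,11,2,10.06
Teleost,Haemulidae,Plectorinchus mediterraneus,species,1,1,
Teleost,Merluciidae,Merluccius merluccius,species,137,5,23768.36
Teleost,Mugilidae,Mugilidae,family,32,3,50948.96
Teleost,Mugilidae,Liza sp.,species,31,2,50565.59
Teleost,Mugilidae,Mugil sp.,species,1,1,383.37
Teleost,Ophidiidae,Ophidion barbatum,species,1,1,32.04
Teleost,Scianidae,Argyrosomus regius,species,3,2,
Teleost,Scombridae,Scomber colias,species,25,4,2998.07
Teleost,Sebastidae,Helicolenus dactylopterus,species,2,1,
Teleost,Serranidae,Serranus hepatus,species,8,1,395.57
Teleost,Soleidae,Soleidae,family,3,2,744.77
Teleost,Soleidae,Solea senegalensis,species,1,1,274.58
Teleost,Soleidae,Solea solea,species,2,1,470.19
Teleost,Sparidae,Sparidae,family,49,9,2133.01
Teleost,Sparidae,Boops boops,species,4,3,280.64
Teleost,Sparidae,Dentex maroccanus,species,1,1,
Teleost,Sparidae,Dentex sp.,species,6,2,
Teleost,Sparidae,Diplodus sp.,species,1,1,52.07
Teleost,Sparidae,Pagellus acarne,species,13,2,915.65
Teleost,Sparidae,Pagellus erythrinus,species,17,3,884.65
Teleost,Sparidae,Sparus aurata,species,5,2,
Teleost,Sparidae,unidentified Sparidae,species,2,2,
Teleost,Trichiuridae,Aphanopus carbo,species,1,1,
Teleost,Triglidae,Triglidae,family,1,1,
Teleost,Unidentified fish,Unidentified fish,family,5,4,
Teleost,,Total teleosts,class,983,13,140929.18
Cephalopod,Loliginidae,Loligo vulgaris,species,1,1,
Cephalopod,Octopodidae,Octopodidae,family,14,4,2913.03
Cephalopod,Octopodidae,Octopus vulgaris,species,8,3,2467.46
Cephalopod,Octopodidae,Eledone cirrhosa,species,6,2,445.57
Cephalopod,,Total cephalopods,class,15,5,2913.03
Crustacean,Brachyura,Brachyura,family,2,2,
Crustacean,Isopoda,Isopoda,family,1,1,
Crustacean,,Total crustaceans,class,3,3,
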