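level,group,taxon,n,mean_d13C,sd_d13C,min_d13C,max_d13C,mean_d15N,sd_d15N,min_d15N,max_d15N
consumer,,Bottlenose dolphins,51,-16.13,0.57,-17.55,-15.30,14.30,0.76,12.80,15.94
group,1,Group 1,52,-16.41,0.45,-17.37,-15.55,14.45,0.81,12.60,15.92
species,1,Diplodus annularis,31,-16.58,0.42,-17.37,-15.56,14.43,0.85,12.60,15.92
species,1,Diplodus bellottii,9,-16.42,0.22,-16.73,-16.05,15.14,0.20,14.74,15.37
species,1,Plectorhinchus mediterraneus,2,-16.64,0.23,-16.80,-16.47,15.00,0.04,14.97,15.02
species,1,Pagellus erythrinus,10,-15.84,0.25,-16.38,-15.55,13.79,0.50,13.24,14.73
group,2,Group 2,120,-18.07,0.67,-19.64,-16.56,10.69,0.96,8.36,13.21
species,2,Merluccius merluccius,31,-18.23,0.66,-19.44,-16.56,10.86,0.89,9.66,13.21
species,2,Scomber colias,20,-18.41,0.43,-19.25,-17.63,10.99,0.45,10.30,11.74
species,2,Scomber scombrus,10,-18.26,0.18,-18.47,-18.02,11.13,0.57,10.31,12.04
species,2,Cepola macrophthalma,9,-17.53,0.27,-18.02,-17.17,10.05,0.40,9.50,10.69
species,2,Conger conger,10,-17.26,0.18,-17.56,-17.00,10.91,0.33,10.15,11.32
species,2,Sardina pilchardus,40,-18.04,0.77,-19.64,-16.99,10.38,1.27,8.36,13.07
species,3,Octopus vulgaris,11,-16.10,0.73,-16.96,-14.36,11.49,0.98,10.02,13.14
species,4,Liza ramada,5,-20.77,4.58,-27.15,-15.28,15.21,0.71,14.00,15.79
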