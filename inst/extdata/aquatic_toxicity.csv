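name,cas,fish_lc50_mg_l,fish_species,fish_predicted,algae_ec50_mg_l,algae_species,algae_predicted,invertebrate_ec50_mg_l,invertebrate_species,invertebrate_predicted
Oxamyl,23135-22-0,3.1,Oncorhynchus mykiss,FALSE,0.9,Raphidocelis subcapitata,FALSE,0.3,Daphnia magna,FALSE
Metam sodium,137-42-8,>0.2,Lepomis macrochirus,FALSE,1.1,Raphidocelis subcapitata,FALSE,1.0,Daphnia magna,FALSE
Fluazaindolizine,1254304-22-7,>30.0,Cyprinodon variegatus,FALSE,46.0,Raphidocelis subcapitata,FALSE,>120,Daphnia magna,FALSE
Fluensulfone,318290-98-1,38.0,Oncorhynchus mykiss,FALSE,0.02,Raphidocelis subcapitata,FALSE,0.8,Daphnia magna,FALSE
Fluopyram,658066-35-4,>1.0,Pimephales promelas,FALSE,>1.1,Skeletonema costatum,FALSE,55.5,Daphnia magna,FALSE
2-Decanone,693-54-9,5.0,Pimephales promelas,TRUE,,,,4.6,Daphnia magna,TRUE
1-Dodecanol,6175-49-1,1.0,Pimephales promelas,FALSE,,,,0.8,Daphnia magna,FALSE
3-Octanol,589-98-0,23.2,Pimephales promelas,TRUE,114.4,Raphidocelis subcapitata,FALSE,184.5,Daphnia magna,FALSE
Octyl acetate,112-14-1,8.2,Pimephales promelas,TRUE,,,,6.4,Daphnia magna,TRUE
2-Undecanone,112-12-9,3.0,Oncorhynchus mykiss,FALSE,>0.2,Raphidocelis subcapitata,FALSE,0.2,Daphnia magna,FALSE
Allicin,539-86-6,23.9,Pimephales promelas,TRUE,,,,38.7,Daphnia magna,TRUE
Diallyl disulphide,2179-57-9,5.0,Pimephales promelas,TRUE,,,,2.3,Daphnia magna,TRUE
Diallyl trisulphide,2050-87-5,1.9,Pimephales promelas,TRUE,,,,0.4,Daphnia magna,TRUE
Dipropyl trisulphide,6028-61-1,1.8,Pimephales promelas,TRUE,,,,0.2,Daphnia magna,TRUE
Methyl propyl trisulphide,17619-36-2,6.8,Pimephales promelas,TRUE,,,,1.0,Daphnia magna,TRUE
trans-Anethole,4180-23-8,7.0,Danio rerio,FALSE,9.6,not reported,FALSE,4.2,Daphnia magna,FALSE
Benzaldehyde,100-52-7,1.1,Lepomis macrochirus,FALSE,33.1,Raphidocelis subcapitata,FALSE,19.7,Daphnia magna,FALSE
trans-Cinnamaldehyde,104-55-2,>20.0,Lepomis macrochirus,FALSE,16.1,Chlorella vulgaris,FALSE,11.5,Daphnia magna,FALSE
Estragole,140-67-0,5.3,Pimephales promelas,TRUE,,,,3.8,Daphnia magna,TRUE
Eugenol,97-53-0,>10.0,Oncorhynchus mykiss,FALSE,15.4,Raphidocelis subcapitata,FALSE,1.1,Daphnia magna,FALSE
cis-Ascaridole,512-85-6,10.9,Pimephales promelas,TRUE,,,,40.3,Daphnia magna,TRUE
Carvacrol,499-75-2,6.2,not reported,FALSE,4.1,Raphidocelis subcapitata,FALSE,6.1,Daphnia magna,FALSE
Carvone,99-49-0,50.0,Danio rerio,FALSE,154.7,Raphidocelis subcapitata,FALSE,249.5,Daphnia magna,FALSE
Thymol,89-83-8,3.0,Oncorhynchus mykiss,FALSE,11.7,Raphidocelis subcapitata,FALSE,4.9,Daphnia magna,FALSE
Geraniol,106-24-1,11.6,Oncorhynchus mykiss,FALSE,48.0,Raphidocelis subcapitata,FALSE,16.1,Daphnia magna,FALSE
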