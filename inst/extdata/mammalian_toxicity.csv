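name,cas,oral_ld50_mg_kg,oral_model,oral_predicted,dermal_ld50_mg_kg,dermal_model,dermal_predicted
Oxamyl,23135-22-0,3,rat,FALSE,5000,rat,FALSE
Metam sodium,137-42-8,896,rat,FALSE,2000,rat,FALSE
Fluazaindolizine,1254304-22-7,940,rat,FALSE,2000,rat,FALSE
Fluensulfone,318290-98-1,671,rat,FALSE,>2000,rat,FALSE
Fluopyram,658066-35-4,>2000,rat,FALSE,2000,rat,FALSE
2-Decanone,693-54-9,7936,rat,FALSE,,,
1-Dodecanol,6175-49-1,>12800,rat,FALSE,>8000,rabbit,FALSE
3-Octanol,589-98-0,>5000,rat,FALSE,>5000,rabbit,FALSE
Octyl acetate,112-14-1,3000,rat,FALSE,>5000,rabbit,FALSE
2-Undecanone,112-12-9,5000,rat,FALSE,>5000,rabbit,FALSE
Allicin,539-86-6,1121,rat,TRUE,,,
Diallyl disulphide,2179-57-9,260,rat,FALSE,3600,rabbit,FALSE
Diallyl trisulphide,2050-87-5,100,rat,FALSE,,,
Dipropyl trisulphide,6028-61-1,800,rat,FALSE,,,
Methyl propyl trisulphide,17619-36-2,496,rat,TRUE,,,
trans-Anethole,4180-23-8,3050,rat,FALSE,>5000,rabbit,FALSE
Benzaldehyde,100-52-7,1300,rat,FALSE,>2000,rabbit,FALSE
trans-Cinnamaldehyde,104-55-2,2225,rat,FALSE,12000,rat,FALSE
Estragole,140-67-0,1230,rat,FALSE,5000,rabbit,FALSE
Eugenol,97-53-0,3000,rat,FALSE,2000,rat,FALSE
cis-Ascaridole,512-85-6,4042,rat,TRUE,,,
Carvacrol,499-75-2,810,rat,FALSE,2700,rabbit,FALSE
Carvone,99-49-0,3710,rat,FALSE,4000,rabbit,FALSE
Thymol,89-83-8,980,rat,FALSE,>2000,rat,FALSE
Geraniol,106-24-1,>4000,rat,FALSE,>5000,rabbit,FALSE
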