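name,cas,aerosols,air,biota,sediment,soil,suspended_particles,water
Oxamyl,23135-22-0,0.0,0.0,0.0,0.0,0.0,0.0,99.9
Metam sodium,137-42-8,0.0,0.0,0.0,0.0,0.0,0.0,99.9
Fluazaindolizine,1254304-22-7,0.0,0.9,0.0,0.0,0.0,0.0,99.0
Fluensulfone,318290-98-1,0.0,0.3,0.0,0.1,6.4,0.0,93.1
Fluopyram,658066-35-4,0.0,0.0,0.0,1.3,59.3,0.0,39.3
2-Decanone,693-54-9,0.0,73.5,0.0,0.5,20.6,0.0,5.4
1-Dodecanol,6175-49-1,0.0,1.0,0.0,2.1,95.9,0.0,0.9
3-Octanol,589-98-0,0.0,31.5,0.0,0.4,19.3,0.0,48.7
Octyl acetate,112-14-1,0.0,77.9,0.0,0.3,14.3,0.0,7.5
2-Undecanone,112-12-9,0.0,32.4,0.0,1.2,52.2,0.0,14.1
Allicin,539-86-6,0.0,0.2,0.0,0.0,1.5,0.0,98.2
Diallyl disulphide,2179-57-9,0.0,98.0,0.0,0.0,0.2,0.0,1.8
Diallyl trisulphide,2050-87-5,0.0,88.3,0.0,0.0,2.7,0.0,8.9
Dipropyl trisulphide,6028-61-1,0.0,39.8,0.0,1.1,49.6,0.0,9.5
Methyl propyl trisulphide,17619-36-2,0.0,70.1,0.0,0.0,3.2,0.0,26.6
trans-Anethole,4180-23-8,0.0,40.4,0.0,0.8,36.3,0.0,22.5
Benzaldehyde,100-52-7,0.0,28.6,0.0,0.0,1.6,0.0,69.8
trans-Cinnamaldehyde,104-55-2,0.0,3.2,0.0,0.2,8.6,0.0,88.0
Estragole,140-67-0,0.0,25.4,0.0,1.1,50.7,0.0,22.7
Eugenol,97-53-0,0.0,3.1,0.0,0.4,18.3,0.0,78.2
cis-Ascaridole,512-85-6,0.0,93.0,0.0,0.0,0.9,0.0,6.1
Carvacrol,499-75-2,0.0,2.7,0.0,1.3,59.2,0.0,36.7
Carvone,99-49-0,0.0,64.1,0.0,0.1,5.7,0.0,30.1
Thymol,89-83-8,0.0,2.5,0.0,1.3,57.8,0.0,38.3
Geraniol,106-24-1,0.0,43.5,0.0,0.5,21.0,0.0,35.0
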