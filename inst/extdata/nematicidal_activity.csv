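name,cas,target_species,ec50_low_mg_ml,ec50_high_mg_ml,qualifier,note
Oxamyl,23135-22-0,Meloidogyne enterolobii,0.028,0.028,eq,
Oxamyl,23135-22-0,Meloidogyne incognita,0.004,0.004,eq,
Oxamyl,23135-22-0,Pratylenchus penetrans,,,eq,66 +/- 2 percent mean corrected mortality at 2 mg/mL (no EC50 reported)
Metam sodium,137-42-8,Meloidogyne incognita,0.008,0.008,eq,values refer to the decomposition volatile metabolite methyl isothiocyanate
Fluazaindolizine,1254304-22-7,Meloidogyne enterolobii,0.200,0.200,gt,
Fluazaindolizine,1254304-22-7,Meloidogyne incognita,0.030,0.030,eq,
Fluensulfone,318290-98-1,Meloidogyne enterolobii,0.026,0.026,eq,
Fluensulfone,318290-98-1,Meloidogyne incognita,0.001,0.001,eq,
Fluopyram,658066-35-4,Meloidogyne enterolobii,0.0004,0.0004,eq,
Fluopyram,658066-35-4,Meloidogyne incognita,0.0001,0.0001,eq,
2-Decanone,693-54-9,Meloidogyne incognita,0.056,0.056,eq,
2-Decanone,693-54-9,Meloidogyne javanica,0.056,0.056,eq,
1-Dodecanol,6175-49-1,Bursaphelenchus xylophilus,0.009,0.009,eq,
3-Octanol,589-98-0,Pratylenchus penetrans,0.680,0.680,eq,
Octyl acetate,112-14-1,Meloidogyne incognita,0.037,0.037,eq,
Octyl acetate,112-14-1,Meloidogyne javanica,0.061,0.061,eq,
2-Undecanone,112-12-9,Meloidogyne incognita,0.021,0.021,eq,
2-Undecanone,112-12-9,Meloidogyne javanica,0.023,0.023,eq,
Allicin,539-86-6,Meloidogyne incognita,0.018,0.018,eq,
Diallyl disulphide,2179-57-9,Bursaphelenchus xylophilus,0.043,0.047,eq,
Diallyl trisulphide,2050-87-5,Bursaphelenchus xylophilus,0.003,0.004,eq,
Dipropyl trisulphide,6028-61-1,Bursaphelenchus xylophilus,0.004,0.005,eq,
Methyl propyl trisulphide,17619-36-2,Bursaphelenchus xylophilus,0.017,0.023,eq,
trans-Anethole,4180-23-8,Meloidogyne incognita,0.170,0.170,eq,
trans-Anethole,4180-23-8,Pratylenchus penetrans,1.780,1.780,eq,
Benzaldehyde,100-52-7,Meloidogyne incognita,0.009,0.009,eq,
Benzaldehyde,100-52-7,Pratylenchus penetrans,0.450,0.450,eq,
trans-Cinnamaldehyde,104-55-2,Bursaphelenchus xylophilus,0.057,0.057,eq,
trans-Cinnamaldehyde,104-55-2,Meloidogyne incognita,0.064,0.064,eq,
Estragole,140-67-0,Meloidogyne incognita,0.230,0.230,eq,
Eugenol,97-53-0,Meloidogyne incognita,0.256,0.256,eq,
Eugenol,97-53-0,Pratylenchus penetrans,1.720,1.720,eq,
cis-Ascaridole,512-85-6,Meloidogyne incognita,0.033,0.033,eq,
Carvacrol,499-75-2,Bursaphelenchus xylophilus,0.097,0.125,eq,
Carvacrol,499-75-2,Meloidogyne incognita,0.112,0.112,eq,
Carvacrol,499-75-2,Pratylenchus penetrans,0.480,0.480,eq,
Carvone,99-49-0,Meloidogyne incognita,0.115,0.115,eq,
Thymol,89-83-8,Bursaphelenchus xylophilus,0.110,0.119,eq,
Thymol,89-83-8,Meloidogyne javanica,0.140,0.140,eq,
Thymol,89-83-8,Pratylenchus penetrans,0.500,0.500,eq,
Geraniol,106-24-1,Bursaphelenchus xylophilus,0.415,0.540,eq,
Geraniol,106-24-1,Meloidogyne incognita,0.158,0.158,eq,
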