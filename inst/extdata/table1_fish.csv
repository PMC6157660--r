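specimen_id,taxon,tissue,age_AD,profile_origin,mass_g,standard_length_cm,cn_ratio,collection_year,aa,element,value_permil
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,,15N,8
fish_1,Exocoetus volitans,muscle,,,334.3,29,,2014,,15N,10.4
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Ala,15N,19.7
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Asp,15N,18.7
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Glu,15N,18
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Gly,15N,-0.4
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Ile,15N,19.9
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Leu,15N,18.6
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Lys,15N,1.8
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Met,15N,9.3
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Phe,15N,3
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Pro,15N,14.2
fish_1,Exocoetus volitans,bone_collagen,,,334.3,29,,2014,Val,15N,22.5
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,,15N,7.3
fish_2,Exocoetus volitans,muscle,,,300.5,28,,2014,,15N,10
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Ala,15N,19.2
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Asp,15N,18.6
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Glu,15N,19.7
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Gly,15N,-0.9
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Ile,15N,20.1
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Leu,15N,18.8
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Lys,15N,2.5
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Met,15N,9.6
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Phe,15N,3.8
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Pro,15N,14.1
fish_2,Exocoetus volitans,bone_collagen,,,300.5,28,,2014,Val,15N,22
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,,15N,6.7
fish_3,Exocoetus volitans,muscle,,,241,25.5,,2014,,15N,10
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Ala,15N,19.7
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Asp,15N,17.8
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Glu,15N,19.3
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Gly,15N,-1.8
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Ile,15N,20.4
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Leu,15N,17.6
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Lys,15N,5.2
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Met,15N,8.9
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Phe,15N,2.5
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Pro,15N,12.8
fish_3,Exocoetus volitans,bone_collagen,,,241,25.5,,2014,Val,15N,21.3
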