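specimen_id,taxon,tissue,age_AD,profile_origin,mass_g,standard_length_cm,cn_ratio,collection_year,aa,element,value_permil
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,,15N,14.9
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Ala,15N,18.8
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Asp,15N,15.6
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Glu,15N,19.2
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Gly,15N,8.5
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Ile,15N,18.6
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Leu,15N,17.4
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Lys,15N,3
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Met,15N,9.7
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Phe,15N,4.1
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Pro,15N,19.4
bird_1,Sula sula,bone_collagen,1913,ZS2,,,,,Val,15N,20.9
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,,15N,14.1
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Ala,15N,17.8
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Asp,15N,16.6
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Glu,15N,19.8
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Gly,15N,8.8
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Ile,15N,18.1
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Leu,15N,16.8
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Lys,15N,7.5
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Met,15N,10.1
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Phe,15N,2.4
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Pro,15N,19.7
bird_2,Sula sula,bone_collagen,1680,ZS2,,,,,Val,15N,21.1
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,,15N,13.3
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Ala,15N,19.6
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Asp,15N,18.6
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Glu,15N,20.9
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Gly,15N,11.9
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Ile,15N,21
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Leu,15N,18.7
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Lys,15N,6
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Phe,15N,4.2
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Pro,15N,23.6
bird_3,Sula sula,bone_collagen,1574,GJ2,,,,,Val,15N,23.7
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,,15N,13.1
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Ala,15N,18.7
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Asp,15N,19
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Glu,15N,19.1
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Gly,15N,11.3
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Ile,15N,20.8
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Leu,15N,18.5
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Lys,15N,5.4
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Phe,15N,4.3
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Pro,15N,21.9
bird_4,Sula sula,bone_collagen,1477,GJ2,,,,,Val,15N,21.7
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,,15N,13.7
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Ala,15N,20.3
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Asp,15N,16.7
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Glu,15N,19.6
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Gly,15N,8.5
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Ile,15N,20.1
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Leu,15N,18.6
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Lys,15N,4
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Met,15N,9.5
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Phe,15N,2.2
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Pro,15N,21.9
bird_5,Sula sula,bone_collagen,1341,ZS2,,,,,Val,15N,22.2
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,,15N,13.3
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Ala,15N,20.1
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Asp,15N,19.1
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Glu,15N,20.6
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Gly,15N,9.7
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Ile,15N,21.7
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Leu,15N,19.7
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Lys,15N,5.4
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Phe,15N,4.6
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Pro,15N,22.3
bird_6,Sula sula,bone_collagen,1082,GJ2,,,,,Val,15N,22
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,,15N,12.2
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Ala,15N,18.4
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Asp,15N,17
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Glu,15N,19
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Gly,15N,9.6
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Ile,15N,21
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Leu,15N,18.9
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Lys,15N,4.1
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Phe,15N,3.5
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Pro,15N,20.4
bird_7,Sula sula,bone_collagen,1020,GJ2,,,,,Val,15N,22
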