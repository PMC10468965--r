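individual_id,prey_category,item_count,wet_mass_g
pondlike_001,fishes,1,15.1
pondlike_001,crustaceans,1,1.8
pondlike_001,gastropods,3,4.4
pondlike_001,insects_arachnids,10,2.9
pondlike_002,insects_arachnids,11,2.8
pondlike_003,fishes,1,5.4
pondlike_003,crustaceans,1,3.6
pondlike_003,insects_arachnids,13,4.2
pondlike_004,fishes,1,8.3
pondlike_004,gastropods,1,0.5
pondlike_004,insects_arachnids,4,0.9
pondlike_005,insects_arachnids,5,1.6
pondlike_006,fishes,1,7.6
pondlike_006,crustaceans,1,1.9
pondlike_006,gastropods,2,2.4
pondlike_006,insects_arachnids,9,2.7
pondlike_007,fishes,2,11.6
pondlike_007,gastropods,1,1.4
pondlike_007,insects_arachnids,11,3.9
pondlike_008,fishes,5,56.8
pondlike_008,crustaceans,3,10.6
pondlike_008,insects_arachnids,6,2.4
pondlike_009,fishes,3,20.5
pondlike_009,insects_arachnids,8,2.9
pondlike_010,crustaceans,1,1.7
pondlike_010,insects_arachnids,7,3.0
pondlike_010,seeds,1,0.2
pondlike_011,crustaceans,4,14.8
pondlike_011,insects_arachnids,5,1.5
pondlike_012,fishes,2,22.9
pondlike_012,reptiles,1,21.8
pondlike_012,crustaceans,2,5.0
pondlike_012,insects_arachnids,12,2.8
pondlike_012,seeds,1,0.3
pondlike_013,fishes,3,18.4
pondlike_013,crustaceans,2,5.7
pondlike_013,gastropods,1,1.9
pondlike_013,insects_arachnids,8,3.1
pondlike_014,crustaceans,1,1.6
pondlike_014,insects_arachnids,6,1.6
pondlike_015,mammals,1,17.6
pondlike_015,gastropods,2,2.7
pondlike_015,insects_arachnids,4,1.0
pondlike_015,seeds,1,0.3
pondlike_016,fishes,1,3.6
pondlike_016,crustaceans,1,2.5
pondlike_016,insects_arachnids,7,2.3
pondlike_017,fishes,1,9.5
pondlike_017,crustaceans,1,2.2
pondlike_017,gastropods,3,4.6
pondlike_017,insects_arachnids,7,2.7
pondlike_018,reptiles,1,22.3
pondlike_018,crustaceans,1,2.6
pondlike_018,gastropods,1,0.8
pondlike_018,insects_arachnids,9,2.6
pondlike_018,seeds,1,0.1
pondlike_019,fishes,3,27.4
pondlike_019,insects_arachnids,8,1.9
pondlike_020,fishes,7,35.5
pondlike_020,crustaceans,1,8.3
pondlike_020,gastropods,1,2.4
pondlike_020,insects_arachnids,6,1.4
pondlike_021,insects_arachnids,4,1.3
pondlike_022,gastropods,1,1.2
pondlike_022,insects_arachnids,9,3.1
pondlike_022,amphibians,1,2.9
pondlike_023,fishes,2,21.4
pondlike_023,crustaceans,2,3.6
pondlike_023,insects_arachnids,5,1.2
pondlike_024,reptiles,1,32.1
pondlike_024,insects_arachnids,12,4.8
pondlike_025,gastropods,1,2.6
pondlike_025,insects_arachnids,5,1.9
pondlike_025,seeds,1,0.1
pondlike_026,fishes,5,36.3
pondlike_026,insects_arachnids,8,2.2
pondlike_027,fishes,4,24.7
pondlike_027,crustaceans,4,8.3
pondlike_027,gastropods,5,7.2
pondlike_027,insects_arachnids,2,0.8
pondlike_028,fishes,7,66.4
pondlike_028,mammals,1,14.7
pondlike_028,crustaceans,1,3.8
pondlike_028,gastropods,3,3.4
pondlike_028,insects_arachnids,1,0.2
pondlike_029,fishes,4,46.9
pondlike_029,insects_arachnids,8,2.3
pondlike_030,fishes,3,31.4
pondlike_030,gastropods,1,0.7
pondlike_030,insects_arachnids,8,3.4
pondlike_ad_001,fishes,1,12.0
pondlike_ad_001,crustaceans,1,2.4
pondlike_ad_001,insects_arachnids,5,1.6
pondlike_ad_002,fishes,2,20.9
pondlike_ad_002,crustaceans,4,7.5
pondlike_ad_002,insects_arachnids,8,2.3
pondlike_ad_003,insects_arachnids,14,3.5
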