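individual_id,prey_category,item_count,wet_mass_g
marshlike_001,crustaceans,8,27.7
marshlike_001,insects_arachnids,1,0.2
marshlike_002,crustaceans,10,23.7
marshlike_002,insects_arachnids,4,1.3
marshlike_003,fishes,2,12.3
marshlike_003,crustaceans,7,26.2
marshlike_003,horseshoe_crabs,5,156.3
marshlike_004,fishes,1,8.4
marshlike_004,crustaceans,4,14.9
marshlike_004,insects_arachnids,5,1.2
marshlike_005,fishes,1,7.9
marshlike_005,insects_arachnids,5,1.7
marshlike_005,amphibians,1,2.5
marshlike_006,crustaceans,3,10.2
marshlike_006,insects_arachnids,6,1.7
marshlike_007,crustaceans,3,6.6
marshlike_007,insects_arachnids,6,2.3
marshlike_008,crustaceans,11,29.9
marshlike_009,crustaceans,6,11.2
marshlike_009,insects_arachnids,5,1.8
marshlike_010,crustaceans,4,11.7
marshlike_010,insects_arachnids,2,1.1
marshlike_011,crustaceans,5,13.4
marshlike_011,insects_arachnids,1,0.4
marshlike_012,crustaceans,9,24.7
marshlike_012,horseshoe_crabs,7,167.2
marshlike_013,crustaceans,2,8.0
marshlike_013,gastropods,2,3.9
marshlike_013,insects_arachnids,5,1.7
marshlike_014,crustaceans,6,18.4
marshlike_014,insects_arachnids,2,0.7
marshlike_015,crustaceans,9,24.0
marshlike_015,gastropods,1,1.6
marshlike_015,seeds,1,0.3
marshlike_016,crustaceans,6,20.1
marshlike_017,crustaceans,9,20.7
marshlike_018,crustaceans,6,19.9
marshlike_019,crustaceans,5,18.2
marshlike_019,insects_arachnids,7,2.1
marshlike_020,crustaceans,12,45.4
marshlike_020,insects_arachnids,5,1.0
marshlike_021,crustaceans,5,12.6
marshlike_021,insects_arachnids,5,1.5
marshlike_022,fishes,1,7.6
marshlike_022,crustaceans,8,33.7
marshlike_022,insects_arachnids,1,0.1
marshlike_023,crustaceans,3,10.6
marshlike_023,insects_arachnids,12,2.9
marshlike_024,crustaceans,4,9.0
marshlike_024,gastropods,3,5.5
marshlike_024,insects_arachnids,1,0.2
marshlike_025,crustaceans,3,7.8
marshlike_025,gastropods,7,11.5
marshlike_025,insects_arachnids,2,0.6
marshlike_026,crustaceans,6,16.5
marshlike_026,amphibians,2,5.5
marshlike_027,crustaceans,12,40.9
marshlike_027,gastropods,3,2.9
marshlike_028,insects_arachnids,7,2.4
marshlike_028,horseshoe_crabs,3,55.4
marshlike_029,crustaceans,7,17.1
marshlike_030,crustaceans,14,48.0
marshlike_031,mammals,11,207.4
marshlike_031,crustaceans,2,4.4
marshlike_031,insects_arachnids,2,0.5
marshlike_032,crustaceans,12,28.8
marshlike_032,insects_arachnids,1,0.4
marshlike_033,crustaceans,4,10.8
marshlike_033,insects_arachnids,5,1.4
marshlike_034,mammals,2,97.3
marshlike_034,crustaceans,3,9.9
marshlike_034,insects_arachnids,1,0.2
marshlike_035,crustaceans,1,6.5
marshlike_035,insects_arachnids,9,2.3
marshlike_036,crustaceans,3,8.0
marshlike_036,insects_arachnids,4,1.2
marshlike_037,crustaceans,16,48.1
marshlike_038,crustaceans,16,55.2
marshlike_038,insects_arachnids,1,0.2
marshlike_038,horseshoe_crabs,1,15.2
marshlike_039,crustaceans,6,18.6
marshlike_039,amphibians,1,4.5
marshlike_040,crustaceans,7,22.3
marshlike_040,insects_arachnids,1,0.2
marshlike_041,crustaceans,10,27.4
marshlike_041,insects_arachnids,4,1.8
marshlike_042,fishes,3,32.5
marshlike_042,crustaceans,4,19.6
marshlike_042,insects_arachnids,2,0.4
marshlike_042,horseshoe_crabs,1,58.3
marshlike_043,fishes,8,70.2
marshlike_043,crustaceans,11,40.2
marshlike_044,crustaceans,9,28.2
marshlike_044,insects_arachnids,5,1.8
marshlike_045,crustaceans,4,10.9
marshlike_045,insects_arachnids,4,1.3
marshlike_046,crustaceans,1,6.0
marshlike_046,insects_arachnids,11,3.8
marshlike_046,horseshoe_crabs,1,13.6
marshlike_047,crustaceans,4,20.3
marshlike_047,insects_arachnids,5,1.5
marshlike_048,crustaceans,14,39.5
marshlike_048,insects_arachnids,1,0.4
marshlike_049,crustaceans,4,11.7
marshlike_049,gastropods,2,2.3
marshlike_049,insects_arachnids,3,0.8
marshlike_050,crustaceans,5,17.6
marshlike_050,insects_arachnids,4,1.1
marshlike_051,crustaceans,5,13.9
marshlike_052,crustaceans,7,18.8
marshlike_052,insects_arachnids,8,2.2
marshlike_053,reptiles,1,11.5
marshlike_053,crustaceans,3,12.5
marshlike_053,insects_arachnids,9,2.7
marshlike_054,fishes,5,38.6
marshlike_054,crustaceans,1,3.7
marshlike_054,insects_arachnids,3,0.9
marshlike_055,crustaceans,3,8.9
marshlike_056,crustaceans,11,31.8
marshlike_057,crustaceans,5,17.0
marshlike_057,insects_arachnids,5,1.6
marshlike_058,fishes,1,7.1
marshlike_058,crustaceans,6,16.8
marshlike_058,insects_arachnids,1,0.2
marshlike_059,crustaceans,8,16.7
marshlike_060,crustaceans,12,32.7
marshlike_060,insects_arachnids,1,0.2
marshlike_061,crustaceans,14,39.9
marshlike_062,crustaceans,8,25.8
marshlike_062,insects_arachnids,2,0.5
marshlike_063,crustaceans,8,17.6
marshlike_063,insects_arachnids,5,1.5
marshlike_064,fishes,4,22.5
marshlike_064,crustaceans,1,6.8
marshlike_064,insects_arachnids,3,0.8
marshlike_064,horseshoe_crabs,1,23.9
marshlike_ad_001,mammals,2,34.5
marshlike_ad_001,crustaceans,8,27.5
marshlike_ad_002,insects_arachnids,1,0.5
marshlike_ad_002,amphibians,15,71.3
marshlike_ad_003,crustaceans,5,11.1
marshlike_ad_003,insects_arachnids,7,2.2
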