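individual_id,population,capture_date,total_length_cm,snout_vent_length_cm,sex,capture_salinity_ppt,recapture
pondlike_001,pondlike,2019-08-12,157.7,76.9,F,0.1,false
pondlike_002,pondlike,2019-07-07,95.1,48.3,M,0.6,false
pondlike_003,pondlike,2019-05-06,169.5,86.5,F,0.1,false
pondlike_004,pondlike,2019-08-09,123.5,58.4,F,2.5,false
pondlike_005,pondlike,2019-07-18,81.8,40.3,M,4.2,false
pondlike_006,pondlike,2019-07-04,103.5,54.0,M,0.2,false
pondlike_007,pondlike,2019-06-30,76.4,39.1,M,1.2,false
pondlike_008,pondlike,2019-06-21,148.3,70.9,M,3.5,false
pondlike_009,pondlike,2019-08-11,72.2,37.8,F,4.2,false
pondlike_010,pondlike,2019-08-27,97.0,47.3,M,3.0,false
pondlike_011,pondlike,2019-05-31,97.9,50.6,F,4.0,false
pondlike_012,pondlike,2019-07-16,125.1,60.4,F,1.5,false
pondlike_013,pondlike,2019-05-20,60.1,31.8,F,0.1,false
pondlike_014,pondlike,2019-06-10,71.3,34.2,F,2.9,false
pondlike_015,pondlike,2019-07-28,130.8,62.7,M,2.9,false
pondlike_016,pondlike,2019-08-13,156.5,78.3,M,3.6,false
pondlike_017,pondlike,2019-05-15,176.9,90.4,F,3.2,false
pondlike_018,pondlike,2019-05-08,66.3,32.6,M,2.4,false
pondlike_019,pondlike,2019-07-03,116.4,61.2,M,4.6,false
pondlike_020,pondlike,2019-08-09,144.2,70.5,M,4.3,false
pondlike_021,pondlike,2019-05-18,158.8,74.7,F,0.8,false
pondlike_022,pondlike,2019-06-12,86.4,41.5,F,3.6,false
pondlike_023,pondlike,2019-08-25,151.7,74.7,F,2.4,false
pondlike_024,pondlike,2019-05-19,66.4,31.9,M,4.3,false
pondlike_025,pondlike,2019-05-18,149.4,76.5,F,2.5,false
pondlike_026,pondlike,2019-07-08,139.8,69.8,F,1.5,false
pondlike_027,pondlike,2019-07-10,140.1,74.0,F,2.3,false
pondlike_028,pondlike,2019-06-04,91.3,48.3,F,4.7,false
pondlike_029,pondlike,2019-06-17,90.4,44.4,F,2.1,false
pondlike_030,pondlike,2019-08-16,170.2,83.3,M,0.1,false
pondlike_ad_001,pondlike,2019-06-05,259.4,135.3,F,4.8,false
pondlike_ad_002,pondlike,2019-05-06,295.8,152.9,F,4.9,false
pondlike_ad_003,pondlike,2019-06-08,208.0,99.0,M,3.9,false
pondlike_em_001,pondlike,2019-06-07,106.3,55.8,M,4.7,false
pondlike_em_002,pondlike,2019-08-27,48.4,22.8,M,4.9,false
pondlike_001,pondlike,2019-09-26,157.7,76.9,F,0.1,true
pondlike_002,pondlike,2019-08-21,95.1,48.3,M,0.6,true
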