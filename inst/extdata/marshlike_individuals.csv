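individual_id,population,capture_date,total_length_cm,snout_vent_length_cm,sex,capture_salinity_ppt,recapture
marshlike_001,marshlike,2019-07-31,147.2,72.8,M,27.3,false
marshlike_002,marshlike,2019-07-13,135.7,69.3,F,3.0,false
marshlike_003,marshlike,2019-08-28,82.6,40.6,M,23.2,false
marshlike_004,marshlike,2019-08-13,153.6,75.7,M,23.9,false
marshlike_005,marshlike,2019-05-14,178.1,92.2,F,12.3,false
marshlike_006,marshlike,2019-06-26,110.7,55.1,M,26.2,false
marshlike_007,marshlike,2019-07-05,157.4,75.9,M,16.6,false
marshlike_008,marshlike,2019-06-21,62.9,30.4,M,25.6,false
marshlike_009,marshlike,2019-05-09,93.4,47.2,M,12.4,false
marshlike_010,marshlike,2019-07-10,147.9,77.9,F,19.6,false
marshlike_011,marshlike,2019-05-10,72.1,35.7,F,20.8,false
marshlike_012,marshlike,2019-06-28,118.4,56.7,M,13.2,false
marshlike_013,marshlike,2019-08-21,119.7,62.0,M,7.1,false
marshlike_014,marshlike,2019-06-30,119.4,56.4,F,15.0,false
marshlike_015,marshlike,2019-05-08,161.2,80.6,M,14.8,false
marshlike_016,marshlike,2019-08-20,122.8,63.5,F,27.7,false
marshlike_017,marshlike,2019-05-26,55.5,26.2,F,25.2,false
marshlike_018,marshlike,2019-07-18,115.5,54.4,F,6.4,false
marshlike_019,marshlike,2019-08-22,159.5,79.5,M,12.6,false
marshlike_020,marshlike,2019-06-27,82.9,40.7,M,26.4,false
marshlike_021,marshlike,2019-08-03,99.5,51.3,F,17.1,false
marshlike_022,marshlike,2019-05-08,173.8,85.5,F,23.2,false
marshlike_023,marshlike,2019-06-17,161.6,77.1,M,26.9,false
marshlike_024,marshlike,2019-05-11,119.3,62.0,M,2.0,false
marshlike_025,marshlike,2019-06-21,94.2,44.9,M,10.1,false
marshlike_026,marshlike,2019-08-09,85.7,41.6,M,6.2,false
marshlike_027,marshlike,2019-05-07,81.9,39.8,F,13.9,false
marshlike_028,marshlike,2019-07-08,96.9,50.5,F,24.4,false
marshlike_029,marshlike,2019-07-21,110.1,52.2,F,24.7,false
marshlike_030,marshlike,2019-08-14,45.0,23.2,M,27.4,false
marshlike_031,marshlike,2019-06-02,151.0,78.6,M,26.5,false
marshlike_032,marshlike,2019-08-27,167.0,82.5,M,24.9,false
marshlike_033,marshlike,2019-07-07,170.1,81.1,M,9.9,false
marshlike_034,marshlike,2019-07-25,122.6,58.7,M,21.6,false
marshlike_035,marshlike,2019-05-03,53.5,26.7,M,22.9,false
marshlike_036,marshlike,2019-06-02,111.9,54.7,F,17.1,false
marshlike_037,marshlike,2019-08-23,162.3,82.3,M,6.7,false
marshlike_038,marshlike,2019-05-14,161.4,83.8,F,4.2,false
marshlike_039,marshlike,2019-08-08,58.7,28.3,M,17.3,false
marshlike_040,marshlike,2019-07-14,127.9,62.3,M,26.6,false
marshlike_041,marshlike,2019-06-03,110.4,52.7,F,20.7,false
marshlike_042,marshlike,2019-07-07,147.7,78.0,M,13.3,false
marshlike_043,marshlike,2019-06-01,158.4,77.4,F,10.8,false
marshlike_044,marshlike,2019-07-22,65.9,32.3,F,10.5,false
marshlike_045,marshlike,2019-06-18,175.0,91.3,M,18.5,false
marshlike_046,marshlike,2019-08-18,174.2,91.6,F,5.0,false
marshlike_047,marshlike,2019-08-19,128.3,63.0,F,17.6,false
marshlike_048,marshlike,2019-05-09,95.2,46.0,F,4.5,false
marshlike_049,marshlike,2019-08-04,148.0,74.0,M,3.1,false
marshlike_050,marshlike,2019-05-04,119.5,60.4,F,19.5,false
marshlike_051,marshlike,2019-08-23,73.7,38.9,M,27.0,false
marshlike_052,marshlike,2019-07-04,53.3,27.2,M,15.8,false
marshlike_053,marshlike,2019-07-14,66.5,32.1,M,16.4,false
marshlike_054,marshlike,2019-05-24,171.7,90.5,M,24.4,false
marshlike_055,marshlike,2019-06-28,118.5,56.2,M,4.2,false
marshlike_056,marshlike,2019-08-11,151.9,72.7,M,26.4,false
marshlike_057,marshlike,2019-06-17,71.6,36.4,F,24.9,false
marshlike_058,marshlike,2019-05-23,170.1,90.1,M,21.6,false
marshlike_059,marshlike,2019-08-06,57.4,29.4,M,21.4,false
marshlike_060,marshlike,2019-07-08,80.4,40.5,M,15.3,false
marshlike_061,marshlike,2019-05-27,45.7,21.9,F,15.6,false
marshlike_062,marshlike,2019-07-20,66.8,32.0,F,20.8,false
marshlike_063,marshlike,2019-06-13,131.8,66.5,M,23.6,false
marshlike_064,marshlike,2019-07-21,165.4,86.6,M,23.0,false
marshlike_ad_001,marshlike,2019-06-08,187.9,93.4,M,6.6,false
marshlike_ad_002,marshlike,2019-05-27,289.9,149.3,M,3.5,false
marshlike_ad_003,marshlike,2019-08-02,185.1,88.3,F,13.7,false
marshlike_em_001,marshlike,2019-07-30,175.6,89.5,M,22.5,false
marshlike_em_002,marshlike,2019-05-19,48.3,25.4,F,24.8,false
marshlike_001,marshlike,2019-09-14,147.2,72.8,M,27.3,true
marshlike_002,marshlike,2019-08-27,135.7,69.3,F,3.0,true
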