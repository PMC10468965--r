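individual_id,population,capture_date,total_length_cm,snout_vent_length_cm,sex,capture_salinity_ppt,recapture
demo_j1,demo,2019-06-01,120,61.5,M,0.5,false
demo_a1,demo,2019-06-03,200,102,F,3.2,false
demo_e1,demo,2019-06-10,95,,unknown,,false
demo_r1,demo,2019-07-01,110,55,M,1,true
demo_j2,demo,2019-07-20,150,74,F,18.5,false
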