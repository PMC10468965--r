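individual_id,prey_category,item_count,wet_mass_g
demo_j1,crustaceans,2,5
demo_j1,insects_arachnids,1,0.3
demo_a1,fishes,1,50
demo_r1,fishes,2,3.5
demo_j2,crustaceans,5,12
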