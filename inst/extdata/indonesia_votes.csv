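round_purpose,option_value,vote_count
price_weight,40%,1
price_weight,45%,5
price_weight,50%,8
price_weight,55%,1
price_weight,60%,1
price_cutoff,25%,3
price_cutoff,50%,9
price_cutoff,75%,2
price_cutoff,100%,2
exclusion_vote_1,macroeconomic-benefit,14
exclusion_vote_1,none,6
exclusion_vote_2,added-value-services,13
exclusion_vote_2,none,7
smart_round_1,quality-assurance,9
smart_round_1,equivalence,4
smart_round_1,stability-formulation,3
smart_round_2,equivalence,8
smart_round_2,stability-formulation,6
smart_round_2,supply-reliability,2
smart_round_3,stability-formulation,10
smart_round_3,supply-reliability,4
smart_round_3,real-world-outcomes,2
smart_round_4,supply-reliability,9
smart_round_4,real-world-outcomes,5
smart_round_4,pharmacovigilance,2
smart_round_5,real-world-outcomes,11
smart_round_5,pharmacovigilance,5
swing_step_1,5%,4
swing_step_1,10%,1
swing_step_1,15%,4
swing_step_1,20%,1
swing_step_1,25%,1
swing_step_1,30%,1
swing_step_1,35%,1
swing_step_1,40%,1
swing_step_1,50%,2
swing_step_2,0%,1
swing_step_2,50%,1
swing_step_2,60%,2
swing_step_2,90%,1
swing_step_2,100%,10
swing_step_3,20%,4
swing_step_3,30%,1
swing_step_3,50%,4
swing_step_3,60%,2
swing_step_3,70%,1
swing_step_3,80%,1
swing_step_3,100%,3
swing_step_4,0%,16
swing_step_5,0%,2
swing_step_5,10%,1
swing_step_5,20%,1
swing_step_5,30%,1
swing_step_5,50%,7
swing_step_5,60%,1
swing_step_5,100%,2
price_weight_adjustment,35%,1
price_weight_adjustment,40%,7
price_weight_adjustment,45%,7
price_cutoff_adjustment,50%,3
price_cutoff_adjustment,100%,9
price_cutoff_adjustment,150%,3
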