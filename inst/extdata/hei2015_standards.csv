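component,max_points,direction,unit,max_score_at,zero_score_at
total_fruits,5,adequacy,cup_eq_per_1000kcal,0.8,0
whole_fruits,5,adequacy,cup_eq_per_1000kcal,0.4,0
total_vegetables,5,adequacy,cup_eq_per_1000kcal,1.1,0
greens_and_beans,5,adequacy,cup_eq_per_1000kcal,0.2,0
whole_grains,10,adequacy,oz_eq_per_1000kcal,1.5,0
dairy,10,adequacy,cup_eq_per_1000kcal,1.3,0
total_protein,5,adequacy,oz_eq_per_1000kcal,2.5,0
seafood_plant_protein,5,adequacy,oz_eq_per_1000kcal,0.8,0
fatty_acids,10,ratio,mufa_pufa_per_sfa,2.5,1.2
refined_grains,10,moderation,oz_eq_per_1000kcal,1.8,4.3
sodium,10,moderation,g_per_1000kcal,1.1,2.0
added_sugars,10,moderation,pct_energy,6.5,26
saturated_fats,10,moderation,pct_energy,8,16
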