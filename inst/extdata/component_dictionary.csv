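cycle,canonical,source
synthetic,total_fruits,total_fruits
synthetic,whole_fruits,whole_fruits
synthetic,total_vegetables,total_vegetables
synthetic,greens_and_beans,greens_and_beans
synthetic,whole_grains,whole_grains
synthetic,refined_grains,refined_grains
synthetic,dairy,dairy
synthetic,total_protein,total_protein
synthetic,seafood_plant_protein,seafood_plant_protein
synthetic,mufa_g,mufa_g
synthetic,pufa_g,pufa_g
synthetic,sfa_g,sfa_g
synthetic,sodium_mg,sodium_mg
synthetic,added_sugars_tsp,added_sugars_tsp
synthetic,energy_kcal,energy_kcal
2017-2018,total_fruits,DR1I_F_TOTAL
2017-2018,whole_fruits,DR1I_F_TOTAL-DR1I_F_JUICE
2017-2018,total_vegetables,DR1I_V_TOTAL+DR1I_V_LEGUMES
2017-2018,greens_and_beans,DR1I_V_DRKGR+DR1I_V_LEGUMES
2017-2018,whole_grains,DR1I_G_WHOLE
2017-2018,refined_grains,DR1I_G_REFINED
2017-2018,dairy,DR1I_D_TOTAL
2017-2018,total_protein,DR1I_PF_MPS_TOTAL+DR1I_PF_EGGS+DR1I_PF_NUTSDS+DR1I_PF_SOY+DR1I_PF_LEGUMES
2017-2018,seafood_plant_protein,DR1I_PF_SEAFD_HI+DR1I_PF_SEAFD_LOW+DR1I_PF_NUTSDS+DR1I_PF_SOY+DR1I_PF_LEGUMES
2017-2018,mufa_g,DR1IMFAT
2017-2018,pufa_g,DR1IPFAT
2017-2018,sfa_g,DR1ISFAT
2017-2018,sodium_mg,DR1ISODI
2017-2018,added_sugars_tsp,DR1I_ADD_SUGARS
2017-2018,energy_kcal,DR1IKCAL
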