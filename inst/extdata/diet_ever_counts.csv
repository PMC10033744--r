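exposure,level,n_no,n_yes
food_meat,never or only occasionally,162,56
food_meat,once or twice per week,662,181
food_meat,most or all days per week,5791,1804
food_meat,NA,18,8
food_seafood,never or only occasionally,499,129
food_seafood,once or twice per week,3296,936
food_seafood,most or all days per week,2812,975
food_seafood,NA,26,9
food_fruits,never or only occasionally,262,104
food_fruits,once or twice per week,2217,679
food_fruits,most or all days per week,4136,1262
food_fruits,NA,18,4
food_vegetables,never or only occasionally,149,63
food_vegetables,once or twice per week,812,235
food_vegetables,most or all days per week,5628,1741
food_vegetables,NA,44,10
food_pulses,never or only occasionally,1397,486
food_pulses,once or twice per week,3929,1097
food_pulses,most or all days per week,1249,447
food_pulses,NA,58,19
food_cereals,never or only occasionally,607,170
food_cereals,once or twice per week,2582,759
food_cereals,most or all days per week,3393,1108
food_cereals,NA,51,12
food_pasta,never or only occasionally,2430,676
food_pasta,once or twice per week,3473,1110
food_pasta,most or all days per week,687,253
food_pasta,NA,43,10
food_rice,never or only occasionally,141,42
food_rice,once or twice per week,633,207
food_rice,most or all days per week,5812,1789
food_rice,NA,47,11
food_butter,never or only occasionally,2895,795
food_butter,once or twice per week,2937,952
food_butter,most or all days per week,749,279
food_butter,NA,52,23
food_margarine,never or only occasionally,3621,1033
food_margarine,once or twice per week,2425,803
food_margarine,most or all days per week,531,195
food_margarine,NA,56,18
food_nuts,never or only occasionally,2837,842
food_nuts,once or twice per week,3238,1006
food_nuts,most or all days per week,523,191
food_nuts,NA,35,10
food_potatoes,never or only occasionally,1119,325
food_potatoes,once or twice per week,4480,1351
food_potatoes,most or all days per week,994,363
food_potatoes,NA,40,10
food_milk,never or only occasionally,1349,438
food_milk,once or twice per week,3072,910
food_milk,most or all days per week,2174,691
food_milk,NA,38,10
food_eggs,never or only occasionally,206,67
food_eggs,once or twice per week,2716,840
food_eggs,most or all days per week,3666,1129
food_eggs,NA,45,13
food_fastfood,never or only occasionally,2510,765
food_fastfood,once or twice per week,3662,1120
food_fastfood,most or all days per week,418,150
food_fastfood,NA,43,14
food_probiotic,never or only occasionally,2664,889
food_probiotic,once or twice per week,2938,856
food_probiotic,most or all days per week,985,292
food_probiotic,NA,46,12
gi_level,poor,2135,731
gi_level,moderate,2731,777
gi_level,good,1552,485
gi_level,NA,215,56
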