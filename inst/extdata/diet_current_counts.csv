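exposure,level,n_no,n_yes
food_meat,never or only occasionally,39,17
food_meat,once or twice per week,130,51
food_meat,most or all days per week,1196,608
food_meat,NA,5,3
food_seafood,never or only occasionally,88,41
food_seafood,once or twice per week,623,313
food_seafood,most or all days per week,653,322
food_seafood,NA,6,3
food_fruits,never or only occasionally,73,31
food_fruits,once or twice per week,456,223
food_fruits,most or all days per week,839,423
food_fruits,NA,2,2
food_vegetables,never or only occasionally,43,20
food_vegetables,once or twice per week,153,82
food_vegetables,most or all days per week,1167,574
food_vegetables,NA,7,3
food_pulses,never or only occasionally,323,163
food_pulses,once or twice per week,741,356
food_pulses,most or all days per week,295,152
food_pulses,NA,11,8
food_cereals,never or only occasionally,107,63
food_cereals,once or twice per week,512,247
food_cereals,most or all days per week,742,366
food_cereals,NA,9,3
food_pasta,never or only occasionally,453,223
food_pasta,once or twice per week,746,364
food_pasta,most or all days per week,166,87
food_pasta,NA,5,5
food_rice,never or only occasionally,26,16
food_rice,once or twice per week,132,75
food_rice,most or all days per week,1206,583
food_rice,NA,6,5
food_butter,never or only occasionally,526,269
food_butter,once or twice per week,645,307
food_butter,most or all days per week,187,92
food_butter,NA,12,11
food_margarine,never or only occasionally,675,358
food_margarine,once or twice per week,550,253
food_margarine,most or all days per week,134,61
food_margarine,NA,11,7
food_nuts,never or only occasionally,558,284
food_nuts,once or twice per week,672,334
food_nuts,most or all days per week,133,58
food_nuts,NA,7,3
food_potatoes,never or only occasionally,234,91
food_potatoes,once or twice per week,903,448
food_potatoes,most or all days per week,225,138
food_potatoes,NA,8,2
food_milk,never or only occasionally,289,149
food_milk,once or twice per week,632,278
food_milk,most or all days per week,442,249
food_milk,NA,7,3
food_eggs,never or only occasionally,45,22
food_eggs,once or twice per week,559,281
food_eggs,most or all days per week,758,371
food_eggs,NA,8,5
food_fastfood,never or only occasionally,519,246
food_fastfood,once or twice per week,736,384
food_fastfood,most or all days per week,103,47
food_fastfood,NA,12,2
food_probiotic,never or only occasionally,588,301
food_probiotic,once or twice per week,581,275
food_probiotic,most or all days per week,193,99
food_probiotic,NA,8,4
gi_level,poor,494,237
gi_level,moderate,526,251
gi_level,good,313,172
gi_level,NA,37,19
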