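nutrient_id,USP,MSP
energy,2001,2085
protein,92,99
total_fat,71,72
carbohydrate,259,271
fiber,30,31
cholesterol,214,237
sfa,18,18
mufa,25,26
pufa,22,23
calcium,1278,1297
iron,14,15
magnesium,358,377
phosphorus,1654,1740
potassium,3390,3628
sodium,1658,1740
zinc,13,13
copper,1.4,1.5
selenium,113,127
vitamin_a,898,914
vitamin_e,10,11
vitamin_d,7.5,9
vitamin_c,129,145
thiamin,1.8,1.9
riboflavin,2,2
niacin,23,25
vitamin_b6,2.2,2.3
vitamin_b12,6.2,7.3
choline,355,378
vitamin_k,140,142
folate,513,527
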