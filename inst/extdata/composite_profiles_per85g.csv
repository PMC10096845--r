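nutrient_id,usda_meat,min_meat,min_poultry,fp_meat,fp_poultry
energy,131,151.27,140.99,166.62,186.43
protein,20.8,24.83,24.93,18.21,16.73
total_fat,4.38,5.17,3.84,8.51,9.68
carbohydrate,0.84,0.02,0.00,3.37,7.52
fiber,0.03,0.00,0.00,0.05,0.37
cholesterol,60.2,68.89,81.86,51.56,55.55
sfa,1.44,1.96,0.78,2.79,1.81
mufa,1.74,2.23,1.20,3.67,3.60
pufa,0.42,0.32,0.88,1.09,2.89
calcium,7.41,11.00,6.60,7.86,10.87
iron,1.65,1.54,0.44,0.98,0.54
magnesium,18.4,21.91,23.72,19.78,20.19
phosphorus,191,215.73,191.60,231.02,202.85
potassium,279,345.56,284.54,372.02,257.44
sodium,299,364.91,318.69,625.03,461.27
zinc,3.45,3.92,0.94,2.21,0.65
copper,0.15,0.07,0.04,0.09,0.04
selenium,24.1,33.18,25.52,28.52,16.71
vitamin_a,41.5,0.59,6.86,2.53,4.58
vitamin_e,0.21,0.23,0.63,0.29,0.73
vitamin_d,0.28,0.16,0.03,0.39,0.11
vitamin_c,0.09,0.00,0.00,0.06,0.53
thiamin,0.18,0.20,0.07,0.26,0.07
riboflavin,0.18,0.21,0.18,0.21,0.15
niacin,4.89,6.91,8.55,5.49,6.24
vitamin_b6,0.33,0.55,0.70,0.31,0.32
vitamin_b12,1.74,1.32,0.23,0.67,0.24
choline,78.0,75.05,64.65,66.28,41.12
vitamin_k,0.90,0.88,1.28,2.21,3.57
folate,NA,4.72,6.09,6.75,8.86
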