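food_code,name,energy_kcal,vitamin_a_ug,vitamin_c_mg,thiamin_mg,riboflavin_mg,niacin_mg,vitamin_b6_mg,folate_ug,vitamin_b12_ug,calcium_mg,iron_mg,zinc_mg,mddw_group,source
rice_boiled,"Rice, boiled",130,0,0,0.02,0.01,0.4,0.09,2,0,10,0.2,0.5,starchy_staples,BGD_FCT
flatbread_wheat,"Flatbread, whole wheat",264,0,0,0.26,0.05,2.8,0.16,15,0,20,2.1,0.9,starchy_staples,BGD_FCT
potato_boiled,"Potato, boiled",87,0,13,0.10,0.02,1.4,0.30,10,0,5,0.3,0.3,starchy_staples,BGD_FCT
lentil_dal,"Lentil dal, cooked",116,1,1.5,0.17,0.07,1.1,0.18,181,0,19,3.3,1.3,beans_peas,BGD_FCT
chickpea_boiled,"Chickpea, boiled",164,1,1.3,0.12,0.06,0.5,0.14,172,0,49,2.9,1.5,beans_peas,BGD_FCT
peanut_roasted,"Peanut, roasted",585,0,0,0.44,0.10,13.5,0.26,97,0,54,2.3,3.3,nuts_seeds,BGD_FCT
sesame_seeds,"Sesame seeds, whole",573,3,0,0.79,0.25,4.5,0.79,97,0,975,14.6,7.8,nuts_seeds,BGD_FCT
milk_cow,"Milk, cow, whole",61,28,0,0.04,0.18,0.10,0.04,5,0.45,113,0.03,0.4,dairy,BGD_FCT
yogurt_plain,"Yogurt, plain",61,27,0.5,0.03,0.14,0.08,0.03,7,0.37,121,0.05,0.6,dairy,BGD_FCT
hilsa_curry,"Hilsa fish curry",250,25,0,0.03,0.10,3.5,0.35,10,2.5,180,2.8,1.1,flesh_foods,BGD_FCT
chicken_curry,"Chicken curry",190,16,0,0.07,0.14,6.0,0.35,6,0.3,15,1.3,1.3,flesh_foods,BGD_FCT
dried_fish,"Dried marine fish",310,40,0,0.05,0.25,6.5,0.40,20,4.0,950,4.5,2.5,flesh_foods,BGD_FCT
egg_boiled,"Hen egg, boiled",155,149,0,0.07,0.51,0.06,0.12,44,1.1,50,1.2,1.1,eggs,BGD_FCT
spinach_cooked,"Spinach, cooked",23,469,9.8,0.08,0.19,0.5,0.24,146,0,136,3.6,0.8,dark_green_leafy_veg,BGD_FCT
amaranth_leaves,"Amaranth leaves, cooked",28,292,41,0.02,0.13,0.6,0.18,57,0,215,2.3,0.9,dark_green_leafy_veg,BGD_FCT
carrot_cooked,"Carrot, cooked",35,852,3.6,0.07,0.04,0.6,0.15,14,0,30,0.3,0.2,vitamin_a_rich_fv,BGD_FCT
ripe_mango,"Mango, ripe",60,54,36,0.03,0.04,0.7,0.12,43,0,11,0.2,0.1,vitamin_a_rich_fv,BGD_FCT
eggplant_cooked,"Eggplant, cooked",33,2,1.3,0.08,0.02,0.6,0.09,14,0,6,0.3,0.1,other_vegetables,BGD_FCT
cabbage_cooked,"Cabbage, cooked",23,5,20,0.06,0.04,0.25,0.11,30,0,48,0.2,0.2,other_vegetables,BGD_FCT
banana_ripe,"Banana, ripe",89,3,8.7,0.03,0.07,0.67,0.37,20,0,5,0.3,0.2,other_fruits,BGD_FCT
guava,"Guava",68,31,228,0.07,0.04,1.1,0.11,49,0,18,0.3,0.2,other_fruits,BGD_FCT
soybean_oil,"Soybean oil",884,0,0,0,0,0,0,0,0,0,0,0,none,BGD_FCT
salmon_fish,"Salmon, cooked",208,12,0,0.23,0.38,8.0,0.60,26,3.2,9,0.3,0.4,flesh_foods,IFCT
milk_cow,"Milk, cow, whole (fallback)",65,30,0,0.05,0.16,0.10,0.04,5,0.50,120,0.05,0.4,dairy,IFCT
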