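food_code,food_name,food_group,is_water_only,energy_kcal,protein_g,fat_g,carb_g,alcohol_g,sfa_g,mufa_g,pufa_g,added_sugar_g,fibre_g,sodium_mg,potassium_mg,calcium_mg,magnesium_mg,iron_mg,vit_a_ug_rae,vit_d_ug,vit_c_mg,heq_total_fruit_cup,heq_whole_fruit_cup,heq_total_veg_cup,heq_greens_beans_cup,heq_whole_grains_oz,heq_refined_grains_oz,heq_dairy_cup,heq_total_protein_oz,heq_seafood_plant_oz
R001,"white rice, cooked",rice,FALSE,161.1,2.5,0.3,37.1,0,0.09,0.12,0.06,0,0.3,1,29,3,7,0.1,0,0,0,0,0,0,0,0,1.3,0,0,0
R002,"brown rice, cooked",rice,FALSE,157,2.8,1,34.2,0,0.3,0.4,0.2,0,1.4,0,95,0,49,0.6,0,0,0,0,0,0,0,1.3,0,0,0,0
R003,rice porridge,rice,FALSE,68.1,1.1,0.1,15.7,0,0.03,0.04,0.02,0,0.1,0,0,0,0,0,0,0,0,0,0,0,0,0,0.55,0,0,0
R004,onigiri (salted rice ball),rice,FALSE,168.4,2.7,0.4,38.5,0,0.12,0.16,0.08,0,0.4,200,31,0,0,0,0,0,0,0,0,0,0,0,1.3,0,0,0
B001,white bread,bread,FALSE,250.5,9,4.1,44.4,0,1.9,1.64,0.82,4,2.3,490,97,26,20,0.6,0,0,0,0,0,0,0,0,3.5,0,0,0
B002,croissant,bread,FALSE,441.2,7.9,26.8,42.1,0,12.2,9.5,2.5,5,1.8,470,0,0,0,0,0,0,0,0,0,0,0,0,3,0,0,0
B003,whole-wheat bread,bread,FALSE,236.4,10.2,4,39.9,0,1.2,1.6,0.8,0,6.1,430,180,0,51,1.3,0,0,0,0,0,0,0,3.5,0,0,0,0
B004,sweet bun (anpan),bread,FALSE,305.8,7,7.8,51.9,0,3.3,3.12,1.56,15,2.7,310,0,0,0,0,0,0,0,0,0,0,0,0,2.8,0,0,0
N001,"udon, cooked",noodles,FALSE,99.6,2.6,0.4,21.4,0,0.12,0.16,0.08,0,0.8,120,0,0,0,0,0,0,0,0,0,0,0,0,0.9,0,0,0
N002,"soba, cooked",noodles,FALSE,124.2,4.8,1,24,0,0.3,0.4,0.2,0,2,0,34,0,27,0.8,0,0,0,0,0,0,0,0.5,0.4,0,0,0
N003,ramen noodles with soup,noodles,FALSE,165.3,5.1,4.9,25.2,0,1.8,1.96,0.98,0,1.1,920,120,0,0,0,0,0,0,0,0,0,0,0,0.9,0,0,0
N004,"spaghetti, cooked",noodles,FALSE,152.5,5.8,0.9,30.3,0,0.27,0.36,0.18,0,1.7,60,0,0,0,0,0,0,0,0,0,0,0,0,1.1,0,0,0
P001,"potato, boiled",potatoes,FALSE,74.9,1.6,0.1,16.9,0,0.03,0.04,0.02,0,1.3,0,340,0,19,0.4,0,0,18,0,0,0.6,0,0,0,0,0,0
P002,"sweet potato, steamed",potatoes,FALSE,127.8,1.2,0.2,30.3,0,0.06,0.08,0.04,0,2.3,0,480,36,0,0,2,0,25,0,0,0.55,0,0,0,0,0,0
P003,"taro, boiled",potatoes,FALSE,59.3,1.5,0.1,13.1,0,0.03,0.04,0.02,0,2.3,0,560,0,0,0,0,0,0,0,0,0.5,0,0,0,0,0,0
P004,konnyaku (devil's tongue jelly),potatoes,FALSE,9.6,0.1,0,2.3,0,0,0,0,0,2.2,0,0,43,0,0,0,0,0,0,0,0.3,0,0,0,0,0,0
L001,tofu (momen),pulses (incl. nuts),FALSE,70.6,6.6,4.2,1.6,0,0.7,0.9,2.2,0,0.4,0,110,86,57,1.5,0,0,0,0,0,0,0,0,0,0,1.2,1.2
L002,natto (fermented soybeans),pulses (incl. nuts),FALSE,195.2,16.5,10,9.8,0,1.5,2.2,5,0,6.7,0,660,90,100,3.3,0,0,0,0,0,0,0.25,0,0,0,2,2
L003,"soybeans, boiled",pulses (incl. nuts),FALSE,181,14.8,9.8,8.4,0,1.4,2.1,5,0,6.6,0,530,79,100,2.2,0,0,0,0,0,0,0.25,0,0,0,1.8,1.8
L004,"peanuts, roasted",pulses (incl. nuts),FALSE,578.6,26.5,47,12.4,0,8.3,24,14.5,0,7.2,0,760,0,200,1.7,0,0,0,0,0,0,0,0,0,0,2,2
V001,"spinach, boiled",total_vegetables,FALSE,26.9,2.6,0.5,3,0,0.15,0.2,0.1,0,3.6,0,490,69,40,0.9,450,0,19,0,0,0.55,0.55,0,0,0,0,0
V002,"cabbage, raw",total_vegetables,FALSE,25.4,1.3,0.2,4.6,0,0.06,0.08,0.04,0,1.8,0,200,43,0,0,0,0,41,0,0,0.5,0,0,0,0,0,0
V003,"carrot, boiled",total_vegetables,FALSE,30.6,0.7,0.2,6.5,0,0.06,0.08,0.04,0,2.8,0,240,0,0,0,720,0,4,0,0,0.5,0,0,0,0,0,0
V004,"tomato, raw",total_vegetables,FALSE,19.3,0.7,0.1,3.9,0,0.03,0.04,0.02,0,1,0,210,0,0,0,45,0,15,0,0,0.45,0,0,0,0,0,0
F001,"apple, raw",fruit,FALSE,55.9,0.2,0.3,13.1,0,0.09,0.12,0.06,0,1.9,0,120,0,0,0,0,0,6,0.45,0.45,0,0,0,0,0,0,0
F002,"mandarin orange, raw",fruit,FALSE,47.7,0.7,0.1,11,0,0.03,0.04,0.02,0,1,0,150,0,0,0,84,0,32,0.5,0.5,0,0,0,0,0,0,0
F003,"banana, raw",fruit,FALSE,91.8,1.1,0.2,21.4,0,0.06,0.08,0.04,0,1.1,0,360,0,32,0,0,0,16,0.45,0.45,0,0,0,0,0,0,0
F004,orange juice (100 %),fruit,FALSE,46.5,0.7,0.1,10.7,0,0.03,0.04,0.02,0,0.2,0,180,0,0,0,0,0,42,0.42,0,0,0,0,0,0,0,0
S001,"salmon, grilled",fish (incl. shellfish),FALSE,180.5,22.3,10.1,0.1,0,2.3,4.4,2.9,0,0,0,440,0,0,0,0,23,0,0,0,0,0,0,0,0,3.5,3.5
S002,"mackerel, grilled",fish (incl. shellfish),FALSE,237.5,20.6,17.1,0.3,0,4.6,6.5,4.3,0,0,0,330,0,0,1.2,0,5.1,0,0,0,0,0,0,0,0,3.5,3.5
S003,"tuna, sashimi",fish (incl. shellfish),FALSE,118.6,26.4,1.4,0.1,0,0.4,0.4,0.4,0,0,0,380,0,0,1.1,0,5,0,0,0,0,0,0,0,0,3.5,3.5
S004,"shrimp, boiled",fish (incl. shellfish),FALSE,80.6,18.7,0.6,0.1,0,0.18,0.24,0.12,0,0,200,0,41,0,0,0,0,0,0,0,0,0,0,0,0,3.5,3.5
M001,"chicken thigh, grilled",meat,FALSE,194.2,16.6,14.2,0,0,4.4,6.7,2.3,0,0,0,290,0,0,0.6,40,0,0,0,0,0,0,0,0,0,3.5,0
M002,"pork loin, pan-fried",meat,FALSE,250.8,19.3,19.2,0.2,0,7.8,8.9,2.1,0,0,0,310,0,0,0.3,0,0,0,0,0,0,0,0,0,0,3.5,0
M003,"beef (karubi), grilled",meat,FALSE,279.3,17.1,23.3,0.3,0,9.2,11.3,0.9,0,0,0,260,0,0,1.4,0,0,0,0,0,0,0,0,0,0,3.5,0
M004,"ham, sliced",meat,FALSE,196.3,16.5,13.9,1.3,0,5.1,6.2,1.5,0,0,1000,0,0,0,0,0,0,0,0,0,0,0,0,0,0,3.5,0
E001,"hen egg, boiled",eggs,FALSE,142.8,12.9,10,0.3,0,3,4.1,1.4,0,0,140,0,0,0,1.8,150,1.8,0,0,0,0,0,0,0,0,2,0
E002,"hen egg, raw",eggs,FALSE,143.1,12.3,10.3,0.3,0,3.1,4.2,1.4,0,0,140,0,0,0,1.8,150,1.8,0,0,0,0,0,0,0,0,2,0
E003,tamagoyaki (rolled omelette),eggs,FALSE,152,10.8,9.2,6.5,0,2.7,3.8,1.3,3,0,450,0,0,0,0,130,1.5,0,0,0,0,0,0,0,0,1.7,0
E004,"quail eggs, boiled",eggs,FALSE,169.5,12.6,13.1,0.3,0,4,5.4,1.7,0,0,210,0,0,0,2.8,480,2.5,0,0,0,0,0,0,0,0,2,0
D001,"milk, whole",dairy,FALSE,66.6,3.3,3.8,4.8,0,2.3,1,0.1,0,0,41,150,110,10,0,38,0.3,0,0,0,0,0,0,0,0.42,0,0
D002,"yogurt, plain",dairy,FALSE,61,3.6,3,4.9,0,1.8,1.2,0.6,0,0,48,170,120,12,0,33,0,0,0,0,0,0,0,0,0.42,0,0
D003,processed cheese,dairy,FALSE,330,22.7,26,1.3,0,16,6.8,0.6,0,0,1100,0,630,0,0,240,0,0,0,0,0,0,0,0,2.3,0,0
D004,ice cream,dairy,FALSE,180.4,3.9,8,23.2,0,4.8,3.2,1.6,16,0,80,0,140,0,0,58,0,0,0,0,0,0,0,0,0.35,0,0
C001,milk chocolate,confectioneries,FALSE,557.7,6.9,34.1,55.8,0,19.9,11.8,1.2,45,3.9,64,440,240,74,0,0,0,0,0,0,0,0,0,0,0.2,0,0
C002,shortcake,confectioneries,FALSE,322.4,6.1,14,43,0,8,5.6,2.8,25,0.9,80,0,32,0,0,120,0,0,0,0,0,0,0,1.2,0.1,0,0
C003,senbei (rice cracker),confectioneries,FALSE,373.8,7.3,1,83.9,0,0.3,0.4,0.2,5,0.6,500,0,0,0,0,0,0,0,0,0,0,0,0,2.5,0,0,0
C004,butter cookie,confectioneries,FALSE,513,5.7,27,61.8,0,13.2,9.5,2.3,30,1.4,270,0,0,0,0,0,0,0,0,0,0,0,0,1.8,0,0,0
Q001,cola,sugar_sweetened_beverages,FALSE,45.6,0,0,11.4,0,0,0,0,11.4,0,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Q002,sports drink,sugar_sweetened_beverages,FALSE,20.4,0,0,5.1,0,0,0,0,5.1,0,31,26,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Q003,sweetened coffee beverage,sugar_sweetened_beverages,FALSE,38.3,0.7,0.3,8.2,0,0.09,0.12,0.06,7.5,0,30,0,22,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Q004,sweetened soda (lemon),sugar_sweetened_beverages,FALSE,40.8,0,0,10.2,0,0,0,0,10.2,0,4,0,0,0,0,0,0,10,0,0,0,0,0,0,0,0,0
A001,beer,alcoholic_beverages,FALSE,38.3,0,0,3.1,3.7,0,0,0,0,0,0,34,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
A002,sake,alcoholic_beverages,FALSE,105.7,0,0,4.9,12.3,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
A003,shochu (25 %),alcoholic_beverages,FALSE,143.5,0,0,0,20.5,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
A004,red wine,alcoholic_beverages,FALSE,71.1,0,0,1.5,9.3,0,0,0,0,0,0,110,0,0,0.4,0,0,0,0,0,0,0,0,0,0,0,0
W001,"green tea, infused",non_energetic_beverages,FALSE,0,0,0,0,0,0,0,0,0,0,0,27,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
W002,barley tea,non_energetic_beverages,FALSE,0,0,0,0,0,0,0,0,0,0,0,6,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
W003,"coffee, black",non_energetic_beverages,FALSE,0,0,0,0,0,0,0,0,0,0,0,65,0,6,0,0,0,0,0,0,0,0,0,0,0,0,0
W004,tap water,non_energetic_beverages,TRUE,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
W005,mineral water,non_energetic_beverages,TRUE,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
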