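component,sr_nutrient_nbr,sr_name,sr_unit
water,255,Water,G
protein,203,Protein,G
carbohydrate,205,"Carbohydrate, by difference",G
fiber,291,"Fiber, total dietary",G
total_fat,204,Total lipid (fat),G
saturated_fat,606,"Fatty acids, total saturated",G
monounsaturated_fat,645,"Fatty acids, total monounsaturated",G
polyunsaturated_fat,646,"Fatty acids, total polyunsaturated",G
thiamin,404,Thiamin,MG
riboflavin,405,Riboflavin,MG
niacin,406,Niacin,MG
pantothenic_acid,410,Pantothenic acid,MG
vitamin_b6,415,Vitamin B-6,MG
folate,417,"Folate, total",UG
vitamin_c,401,"Vitamin C, total ascorbic acid",MG
vitamin_a,320,"Vitamin A, RAE",UG
vitamin_e,323,Vitamin E (alpha-tocopherol),MG
calcium,301,"Calcium, Ca",MG
iron,303,"Iron, Fe",MG
magnesium,304,"Magnesium, Mg",MG
phosphorus,305,"Phosphorus, P",MG
potassium,306,"Potassium, K",MG
sodium,307,"Sodium, Na",MG
zinc,309,"Zinc, Zn",MG
copper,312,"Copper, Cu",MG
manganese,315,"Manganese, Mn",MG
selenium,317,"Selenium, Se",UG
cholesterol,601,Cholesterol,MG
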