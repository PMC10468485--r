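product_id,name,subgroup,nova_group,basis,energy_kcal,total_fat_g,sat_fat_g,trans_fat_g,sodium_mg,total_sugars_g,added_sugars_g,ingredients_text
P001,Chocolate sandwich cookie,Sweet cookies,4,per_100g,480,20,9,0,350,38,,"farinha de trigo, acucar, gordura vegetal hidrogenada, cacau em po, aroma artificial de baunilha, lecitina de soja, bicarbonato de sodio"
P002,Cola soft drink,Carbonated beverages,4,per_100ml,42,,,,10,10.6,,"agua gaseificada, acucar, corante caramelo iv, acido fosforico, aroma natural, cafeina"
P003,Diet cola,Carbonated beverages,4,per_100ml,0,,,,12,,,"agua gaseificada, corante caramelo iv, acido fosforico, aspartame, acessulfame de potassio, aroma natural"
P004,Mozzarella cheese,Cheese,3,per_100g,300,22,14,0,520,,,"leite, sal, fermento lateo, coalho"
P005,Egg pasta,Pasta,1,per_100g,360,2,0.5,0,20,,,"farinha de trigo enriquecida com ferro e acido folico, ovos, corante natural urucum, curcuma"
P006,Olive oil,Oils,2,per_100ml,884,100,14,0,0,0,0,"azeite de oliva extra virgem"
P007,Strawberry yogurt drink,Dairy beverages,4,per_100ml,80,2,1.2,0,45,11,,"leite, acucar, preparado de morango, amido modificado, carmim, aroma natural de morango, sorbato de potassio"
P008,Canned sardines,Others,3,per_100g,180,10,2.5,0,450,,,"sardinha, agua, sal"
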