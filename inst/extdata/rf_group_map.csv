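sr_category,rf_group
Vegetables and Vegetable Products,vegetables
Legumes and Legume Products,legumes
Cereal Grains and Pasta,grains
Fruits and Fruit Juices,fruits
Beef Products,beef
Lamb Veal and Game Products,lamb
Poultry Products,poultry
Pork Products,pork
Finfish and Shellfish Products,fish
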