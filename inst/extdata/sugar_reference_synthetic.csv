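subgroup,added_sugars_g_per_100
Sweet cookies,25
Cakes and sweet pies,30
Chocolate,45
Sweets in general,50
Carbonated beverages,10
Other sugary drinks,9
Dairy beverages,11
Ice cream,20
Bread,4
Salted biscuits,2
Sauces and spreads,8
Ready meals,2
Pizza lasagna or pastry,2
Cold cuts and sausages,1
Margarine,0
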