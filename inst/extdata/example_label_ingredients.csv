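product_id,long_name,usda_category,ingredients_text
496925,,pb_milk_alternative,"Organic almond milk (filtered water, organic almonds), organic cane sugar, organic locust bean gum, sea salt, natural flavors, sunflower lecithin, tricalcium phosphate, gellan gum, potassium citrate, organic vanilla extract, vitamin A palmitate, ergocalciferol (vitamin D2), DF-alpha-tocopherol acetate (vitamin E), cyanocobalamin (vitamin B12)"
1097251,,pb_milk_alternative,"Flax milk (filtered water, cold pressed flax oil), pea protein isolate, cane sugar, tapioca starch, vanilla extract, natural flavors sunflower lecithin, sea salt, gellan gum, xanthan gum, vitamin A palmitate, vitamin D2, vitamin B12"
411752,,pb_milk_alternative,"Cashew milk (filtered water, cashews), contains 2% or less of: almond butter, vitamin & mineral blend (incl. calcium carbonate, vitamin E acetate, vitamin A palmitate, vitamin D2), sea salt, locust bean gum, sunflower lecithin, natural flavor, gellan gum, ascorbic acid"
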