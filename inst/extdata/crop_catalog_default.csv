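crop_name,functional_type,edible,forage_only,f_h2o,alpha,f_ref,gamma_calorie,gamma_carb,gamma_protein,gamma_fat,retail_product
winter_wheat,cereal,TRUE,FALSE,0.12,0.78,1.0,0.00364,0.763,0.103,0.0098,wheat_flour
spring_wheat,cereal,TRUE,FALSE,0.12,0.78,1.0,0.00364,0.763,0.103,0.0098,wheat_flour
spring_barley,cereal,TRUE,FALSE,0.10,0.65,1.0,0.00352,0.777,0.099,0.0116,barley_flour
winter_barley,cereal,TRUE,FALSE,0.10,0.65,1.0,0.00352,0.777,0.099,0.0116,barley_flour
oat,cereal,TRUE,FALSE,0.09,0.55,1.0,0.00379,0.663,0.169,0.0690,oat_flakes
rye,cereal,TRUE,FALSE,0.11,0.80,1.0,0.00349,0.757,0.104,0.0160,rye_flour
triticale,cereal,TRUE,FALSE,0.11,0.78,1.0,0.00357,0.760,0.104,0.0130,triticale_flour
maize_grain,cereal,TRUE,FALSE,0.11,0.80,1.0,0.00361,0.766,0.069,0.0390,maize_flour
pea,annual_legume,TRUE,FALSE,0.11,1.0,1.0,0.00341,0.600,0.246,0.0120,dried_peas
faba_bean,annual_legume,TRUE,FALSE,0.11,1.0,1.0,0.00341,0.580,0.260,0.0150,dried_beans
lupin,annual_legume,TRUE,FALSE,0.10,1.0,1.0,0.00371,0.402,0.364,0.0970,dried_lupin
soybean,annual_legume,TRUE,FALSE,0.085,1.0,1.0,0.00446,0.302,0.365,0.1990,dried_soybeans
oilseed_rape,annual_broadleaf,TRUE,FALSE,0.0,0.40,1.0,0.00884,0.0,0.0,1.0,rapeseed_oil
sunflower,annual_broadleaf,TRUE,FALSE,0.0,0.40,1.0,0.00884,0.0,0.0,1.0,sunflower_oil
flax,annual_broadleaf,TRUE,FALSE,0.0,0.33,1.0,0.00884,0.0,0.0,1.0,linseed_oil
potato,annual_broadleaf,TRUE,FALSE,0.79,1.0,0.81,0.00077,0.175,0.020,0.0010,raw_potatoes
sugar_beet,annual_broadleaf,TRUE,FALSE,0.0,0.65,1.0,0.00387,0.998,0.0,0.0,sugar
swede,annual_broadleaf,TRUE,FALSE,0.90,1.0,0.85,0.00037,0.086,0.011,0.0020,raw_swede
ley,ley,FALSE,TRUE,,,,,,,,forage
ryegrass,ley,FALSE,TRUE,,,,,,,,forage
forage_rape,annual_broadleaf,FALSE,TRUE,,,,,,,,forage
maize_silage,cereal,FALSE,TRUE,,,,,,,,forage
fallow,fallow,FALSE,FALSE,,,,,,,,none
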