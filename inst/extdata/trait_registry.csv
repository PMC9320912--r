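"name","long_name","category","units","direction","strictly_positive"
"SL","seedling length","growth","cm",1,TRUE
"RL","root length","growth","cm",1,TRUE
"RN","root number","growth","count",1,TRUE
"SFW","seedling fresh weight","growth","g",1,TRUE
"RFW","root fresh weight","growth","g",1,TRUE
"PB","plant biomass","growth","g",1,TRUE
"RSR","root-shoot ratio","growth","ratio",1,TRUE
"Chl_a","chlorophyll a content","photosynthetic","mg g-1 FW",1,TRUE
"Chl_b","chlorophyll b content","photosynthetic","mg g-1 FW",1,TRUE
"Chl_ab","chlorophyll a+b content","photosynthetic","mg g-1 FW",1,TRUE
"Chl_ratio","chlorophyll a:b ratio","photosynthetic","ratio",1,TRUE
"Pn","net photosynthetic rate","photosynthetic","uM m-2 s-1",1,TRUE
"Ci","intercellular CO2 concentration","photosynthetic","uM M-1",-1,TRUE
"Gs","stomatal conductance","photosynthetic","mol m-2 s-1",1,TRUE
"Tr","transpiration rate","photosynthetic","mM m-2 s-1",1,TRUE
"WUE","water use efficiency","photosynthetic","ratio",1,TRUE
"Rubisco","ribulose-1,5-bisphosphate carboxylase activity","photosynthetic","M m-2 s-1",1,TRUE
"MDA","malondialdehyde content","membrane","uM g-1 FW",-1,TRUE
"MSI","membrane stability index","membrane","%",1,TRUE
"O2","superoxide production rate","ROS","uM min-1 g-1 FW",-1,TRUE
"H2O2","hydrogen peroxide content","ROS","uM g-1 FW",-1,TRUE
"SOD","superoxide dismutase activity","antioxidant","Unit g-1 protein",1,TRUE
"POD","peroxidase activity","antioxidant","Unit g-1 protein",1,TRUE
"CAT","catalase activity","antioxidant","uM min-1 g-1 protein",1,TRUE
"APX","ascorbate peroxidase activity","antioxidant","uM min-1 g-1 protein",1,TRUE
"Pro","proline content","osmotic","ug g-1 FW",1,TRUE
"Put","putrescine concentration","polyamine","nM g-1 FW",1,TRUE
"Spd","spermidine concentration","polyamine","nM g-1 FW",1,TRUE
"Spm","spermine concentration","polyamine","nM g-1 FW",1,TRUE
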