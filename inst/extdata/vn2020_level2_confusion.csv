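,Residence1,Residence2,RicePaddies,WoodyCrops,OtherCrops,InHouseCrops,Grassland,BarrenLand,Scrubland,DeciduousBroadleafForest,EvergreenBroadleafForest,EvergreenNeedleleafForest,PlantationLand,MangroveForest,InlandWetland,OpenWater,Aquaculture,BambooAreas
Residence1,804,137,3,0,10,0,2,6,1,0,0,0,0,0,0,0,3,0
Residence2,212,848,4,17,12,3,1,7,8,0,0,0,0,0,2,0,1,0
RicePaddies,0,1,932,5,27,1,3,5,0,2,0,0,5,0,0,0,0,0
WoodyCrops,0,2,12,674,45,0,6,3,6,5,7,0,35,2,0,0,0,0
OtherCrops,0,2,27,26,801,2,1,5,11,3,2,0,15,0,1,0,0,0
InHouseCrops,15,34,9,15,26,1044,0,26,84,6,0,0,0,0,0,0,0,0
Grassland,0,0,14,39,45,0,975,17,9,2,24,0,43,0,0,0,0,1
BarrenLand,16,14,11,8,12,0,40,960,10,6,1,0,5,0,0,1,4,0
Scrubland,0,1,3,13,8,0,17,16,898,33,12,0,13,0,0,0,2,0
DeciduousBroadleafForest,1,0,1,21,5,0,0,2,17,980,30,4,35,0,0,0,0,0
EvergreenBroadleafForest,0,0,1,8,1,0,2,1,1,2,355,1,41,0,0,0,0,6
EvergreenNeedleleafForest,0,0,0,37,0,0,0,0,5,9,202,1045,19,0,0,0,0,0
PlantationLand,0,0,12,12,16,0,1,1,0,2,39,0,603,2,3,0,0,0
MangroveForest,0,6,2,7,2,0,0,1,0,0,2,0,17,1036,1,1,3,0
InlandWetland,0,3,7,160,35,0,0,0,0,0,0,0,100,2,1042,0,95,0
OpenWater,1,0,2,0,0,0,0,0,0,0,0,0,0,1,0,1028,3,0
Aquaculture,1,2,10,0,3,0,0,0,0,0,0,0,0,6,1,20,939,0
BambooAreas,0,0,0,8,2,0,2,0,0,0,376,0,119,1,0,0,0,1043
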