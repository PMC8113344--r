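,Residence,RicePaddies,Cropland,Grassland,BarrenLand,Scrubland,ForestLand,Wetland,OpenWater,Aquaculture
Residence,988,3,21,1,6,4,0,2,0,2
RicePaddies,1,988,26,1,4,1,8,0,0,1
Cropland,27,18,772,1,28,38,17,1,0,0
Grassland,1,15,57,990,15,8,64,0,0,0
BarrenLand,25,8,14,44,980,11,11,0,0,1
Scrubland,0,4,23,13,17,986,44,1,0,3
ForestLand,1,2,14,0,0,2,853,0,0,0
Wetland,3,2,119,0,0,0,53,1040,0,44
OpenWater,0,3,0,0,0,0,0,1,1031,4
Aquaculture,4,7,4,0,0,0,0,5,19,995
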