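class,code,habitat,cultivated,construction,unused,sandy
sandy,6,0.1,0.1,0.3,0.3,0.1
forest_grassland,2,1,0.7,0.6,0.6,0.7
water,3,0.9,0.6,0.2,0.4,0.3
unused,5,0.1,0.1,0.3,0.1,0.6
cultivated,1,0.4,0.3,0.5,0.4,0.3
construction,4,0,0.1,0.3,0.2,0
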