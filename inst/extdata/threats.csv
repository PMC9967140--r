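threat,code,d_max_km,weight,decay
cultivated,1,4,0.6,linear
construction,4,8,0.9,exponential
unused,5,6,0.5,linear
sandy,6,6,0.75,exponential
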