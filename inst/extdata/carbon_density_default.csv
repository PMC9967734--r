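class,above,below,soil,dead
cultivated,10.1,26.8,147,0
forest,11.46,31.32,173.9,2.02
grassland,7.96,51,74.6,2.84
water,8.72,2.21,23.01,0
construction,8.75,4.39,27.78,1.16
unutilized,10.03,0,44.79,0
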