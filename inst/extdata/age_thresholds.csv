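species,unit,infant,child,adolescent,young_adult,adult,aged
dog,month,0.75,1.5,6,12,24,100
human,year,0.08,2,12,16,21,60
mouse,week,1,3,5,7,10,45
nonhuman primate,month,0.5,6,36,48,72,240
rat,week,1.25,4,7,12,25,200
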