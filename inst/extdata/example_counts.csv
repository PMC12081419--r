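field_index,length_um,width_um,mineral_class
3,2.4,0.25,amosite
17,5.1,0.4,crocidolite
17,1.6,0.1,amosite
42,0.8,0.05,chrysotile
60,3.3,0.3,amosite
88,12.0,0.9,crocidolite
95,2.1,0.2,amosite
101,1.0,0.08,amosite
104,4.7,0.35,non_asbestos
110,2.9,0.22,crocidolite
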