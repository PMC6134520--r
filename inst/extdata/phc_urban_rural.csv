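year,population_urban,population_rural,institutions_urban,institutions_rural,beds_urban,beds_rural,health_workers_urban,health_workers_rural
2012,711820,642220,121132,791488,158712,1165558,684900,2752272
2013,731110,629610,127508,787860,147793,1202115,729207,2784986
2014,749160,618660,132269,785066,149047,1232150,757613,2779140
2015,771160,603460,140686,780084,153959,1259883,809933,2793229
2016,792980,589730,147745,778773,155769,1286171,869712,2812849
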