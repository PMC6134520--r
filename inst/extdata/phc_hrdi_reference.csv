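year,resource,east,central,west,nation
2012,institutions,0.4270,0.3506,0.1822,0.2536
2013,institutions,0.4286,0.3501,0.1819,0.2536
2014,institutions,0.4291,0.3488,0.1820,0.2535
2015,institutions,0.4292,0.3495,0.1820,0.2537
2016,institutions,0.4320,0.3499,0.1821,0.2544
2012,beds,0.5834,0.5372,0.2668,0.3679
2013,beds,0.5854,0.5430,0.2768,0.3741
2014,beds,0.5827,0.5632,0.2847,0.3817
2015,beds,0.5895,0.5833,0.2885,0.3895
2016,beds,0.5947,0.5958,0.2941,0.3960
2012,health_workers,1.8040,1.3125,0.5952,0.9550
2013,health_workers,1.8561,1.3174,0.6099,0.9738
2014,health_workers,1.8488,1.3217,0.6195,0.9774
2015,health_workers,1.8821,1.3316,0.6327,0.9927
2016,health_workers,1.9274,1.3438,0.6464,1.0113
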