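year,institutions,institutions_per_1000,institutions_per_km2,beds,beds_per_1000,beds_per_km2,health_workers,health_workers_per_1000,health_workers_per_km2
2012,912620,0.6771,0.0950,1324270,0.9825,0.1378,3437172,2.5500,0.3577
2013,915368,0.6755,0.0952,1349908,0.9961,0.1405,3514193,2.5932,0.3657
2014,917335,0.6733,0.0955,1381197,1.0138,0.1437,3536754,2.5959,0.3680
2015,920770,0.6717,0.0958,1413842,1.0313,0.1471,3603162,2.6284,0.3749
2016,926518,0.6715,0.0964,1441940,1.0450,0.1500,3682561,2.6688,0.3832
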