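pair,tec,tc,ptec,sec,tfpc
2012-2013,1.047,0.973,0.996,1.051,1.018
2013-2014,1.106,0.878,1.058,1.045,0.971
2014-2015,1.117,0.871,0.976,1.145,0.973
2015-2016,0.976,1.039,0.983,0.992,1.014
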