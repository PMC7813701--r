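cohort,hemisphere,a,b,c,d
AD,left,100,42,6,51
AD,right,99,41,11,48
MCI,left,100,192,12,339
MCI,right,83,197,11,352
HC,left,26,78,4,373
HC,right,18,81,2,380
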