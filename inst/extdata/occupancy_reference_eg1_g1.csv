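protein,stage,nuclear_rel_pct,nuclear_copies,bound_frac_spotbleach,bound_frac_frap,residence_time,longterm_frac,pub_bound_copies,pub_per_mb,pub_longterm_per_mb
SMC4,early_G1,104,178000,0.21,0.19,28,0.13,33820,2.1,0.3
NCAPH,early_G1,103,127000,0.15,0.11,45,0.09,13970,0.9,0.1
NCAPH2,early_G1,99,25400,0.22,NA,NA,NA,5588,0.4,NA
CTCF,early_G1,102,125500,0.5,0.62,125,0.32,77810,4.9,1.6
RAD21,early_G1,63,151000,0.41,0.53,155,0.28,80030,5.1,1.4
STAG1,early_G1,100,53500,0.37,0.62,244,0.27,33170,2.1,0.6
STAG2,early_G1,56,102000,0.37,0.47,108,0.07,47940,3.0,0.2
SMC4,G1,100,174000,0.1,NA,NA,NA,17400,NA,NA
NCAPH,G1,100,125000,0.09,NA,NA,NA,11250,NA,NA
NCAPH2,G1,100,25600,0.02,NA,NA,NA,512,NA,NA
CTCF,G1,100,124000,0.72,0.72,139,0.488,89280,5.7,2.8
RAD21,G1,100,238000,0.59,0.77,172,0.277,183260,11.6,3.2
STAG1,G1,100,53500,0.59,0.76,276,0.39,40660,2.6,1.0
STAG2,G1,100,183000,0.5,0.71,126,0.107,129930,8.2,0.9
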