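stat,MG,SP,MO3,MO5,MO7,BI
LSD_05,8.03,1.61,7.47,7.20,7.84,5.46
SEm,2.89,0.58,2.68,2.58,2.80,1.97
SEd,4.08,0.89,3.68,3.65,3.97,2.79
CV,15.73,15.74,11.79,9.71,9.61,9.47
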