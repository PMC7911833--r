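condition,zygosity,n_affected,n_unaffected
gp,MZ,196,811
gp,DZ,178,848
migraine,MZ,70,937
migraine,DZ,69,957
headache,MZ,141,866
headache,DZ,133,893
rap,MZ,140,866
rap,DZ,123,902
lbp,MZ,79,470
lbp,DZ,80,677
pp,MZ,68,938
pp,DZ,59,966
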