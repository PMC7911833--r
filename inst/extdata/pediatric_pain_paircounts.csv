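condition,zygosity,n_concordant,n_discordant,n_neither
gp,MZ,61,74,368
gp,DZ,41,96,376
migraine,MZ,16,38,449
migraine,DZ,8,53,452
headache,MZ,33,75,395
headache,DZ,22,89,402
rap,MZ,33,73,396
rap,DZ,17,88,407
lbp,MZ,19,41,213
lbp,DZ,10,59,308
pp,MZ,14,40,448
pp,DZ,6,47,459
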