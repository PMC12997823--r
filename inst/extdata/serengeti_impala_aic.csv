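model,level,df,aic,delta_aic
0,landscape,4,53802,649
Gf,landscape,6,53742,589
Gr,landscape,6,53499,346
Gfr,landscape,8,53427,274
Sf,landscape,10,53734,582
Sr,landscape,10,53211,58
Sfr,landscape,14,53152,0
0,homerange,6,56092,1380
Gf,homerange,8,55211,498
Gr,homerange,8,55839,1127
Gfr,homerange,10,55041,329
Sf,homerange,12,54968,256
Sr,homerange,12,55554,841
Sfr,homerange,16,54712,0
Tf,homerange,12,55211,499
Tr,homerange,12,55845,1132
Tfr,homerange,16,55046,333
STf,homerange,16,54969,256
STr,homerange,16,55559,847
STfr,homerange,22,54717,5
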