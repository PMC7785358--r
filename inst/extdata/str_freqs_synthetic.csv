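locus,allele,freq
FGA,13,0.0229
FGA,14,0.029
FGA,15,0.0357
FGA,16,0.0427
FGA,17,0.0498
FGA,18,0.0564
FGA,19,0.0622
FGA,20,0.0667
FGA,21,0.0695
FGA,22,0.0705
FGA,23,0.0695
FGA,24,0.0667
FGA,25,0.0622
FGA,26,0.0564
FGA,27,0.0498
FGA,28,0.0427
FGA,29,0.0357
FGA,30,0.029
FGA,31,0.0229
FGA,32,0.0176
FGA,33,0.0131
FGA,34,0.0095
FGA,35,0.0067
FGA,36,0.0046
FGA,37,0.0031
FGA,38,0.002
FGA,39,0.0013
FGA,40,8e-04
FGA,41,5e-04
FGA,42,3e-04
FGA,43,2e-04
FGA,44,1e-04
FGA,45,1e-04
FGA,46,1e-04
FGA,47,1e-04
FGA,48,1e-04
FGA,49,1e-04
FGA,50,1e-04
FGA,51,1e-04
SE33,7,0.0105
SE33,8,0.0135
SE33,9,0.0171
SE33,10,0.0212
SE33,11,0.0257
SE33,12,0.0306
SE33,13,0.0356
SE33,14,0.0407
SE33,15,0.0455
SE33,16,0.0499
SE33,17,0.0536
SE33,18,0.0564
SE33,19,0.0581
SE33,20,0.0587
SE33,21,0.0581
SE33,22,0.0564
SE33,23,0.0536
SE33,24,0.0499
SE33,25,0.0455
SE33,26,0.0407
SE33,27,0.0356
SE33,28,0.0306
SE33,29,0.0257
SE33,30,0.0212
SE33,31,0.0171
SE33,32,0.0135
SE33,33,0.0105
SE33,34,0.0079
SE33,35,0.0059
SE33,36,0.0043
SE33,37,0.0031
SE33,38,0.0022
SE33,39,0.0015
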