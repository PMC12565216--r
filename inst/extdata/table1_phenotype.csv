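group,genotype,diet,n,variable,mean,sd
WT_SD,WT,SD,7,bw_gain,120.5,15.5
WT_SD,WT,SD,7,energy_intake,239.4,18.1
WT_SD,WT,SD,7,fer,122.7,19.0
WT_SD,WT,SD,7,bun,55.16,14.85
WT_SD,WT,SD,7,creatinine,0.23,0.07
WT_WD,WT,WD,16,bw_gain,151.4,35.7
WT_WD,WT,WD,16,energy_intake,262.8,28.3
WT_WD,WT,WD,16,fer,147.4,38.1
WT_WD,WT,WD,16,bun,20.4,5.0
WT_WD,WT,WD,16,creatinine,0.19,0.1
KO_SD,KO,SD,7,bw_gain,100.1,18.7
KO_SD,KO,SD,7,energy_intake,305.4,72.9
KO_SD,KO,SD,7,fer,90.5,36.8
KO_SD,KO,SD,7,bun,69.7,57.8
KO_SD,KO,SD,7,creatinine,0.37,0.12
KO_WD,KO,WD,15,bw_gain,147.5,68.8
KO_WD,KO,WD,15,energy_intake,358.8,185.7
KO_WD,KO,WD,15,fer,144.95,80.3
KO_WD,KO,WD,15,bun,42.3,10.5
KO_WD,KO,WD,15,creatinine,0.22,0.1
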