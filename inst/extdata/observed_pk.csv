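scenario,parameter,unit,observed
healthy_750,tmax,h,3
healthy_750,cmax,ng/mL,681
healthy_750,auc,ng/mL.h,7150
healthy_250,tmax,h,1.5
healthy_250,cmax,ng/mL,371
healthy_250,auc,ng/mL.h,2940
itraconazole,cmax_ratio,fold,1.34
itraconazole,auc_ratio,fold,1.71
rifampin,cmax_ratio,fold,0.39
rifampin,auc_ratio,fold,0.17
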