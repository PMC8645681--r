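tissue,f_water,f_neutral_lipid,f_phospholipid
adipose,0.180,0.7900,0.00200
bone,0.439,0.0174,0.00160
brain,0.770,0.0391,0.05330
gut,0.718,0.0487,0.01630
heart,0.758,0.0115,0.01660
kidney,0.783,0.0207,0.01620
liver,0.745,0.0348,0.02520
lung,0.811,0.0030,0.00900
muscle,0.760,0.0238,0.00720
skin,0.718,0.0284,0.01110
spleen,0.788,0.0201,0.01980
pancreas,0.664,0.0403,0.00930
plasma,0.945,0.0035,0.00225
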