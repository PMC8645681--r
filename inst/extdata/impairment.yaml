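# Disease-stage multipliers applied to the healthy mean physiology.
# Literature-typical values for cirrhosis (Child-Pugh A/B/C) and chronic kidney
# disease virtual populations; the declared calibration surface for the
# drug-disease interaction scenarios.
hi_cp_a:
  liver_size: 0.90
  enzyme:
    CYP3A4: 0.70
    CYP3A5: 0.70
    CYP2D6: 0.90
  enterocyte_cyp3a4: 0.95
  albumin: 0.85
  hematocrit: 0.95
  gfr: 1.00
  hepatic_flow: 0.95
hi_cp_b:
  liver_size: 0.82
  enzyme:
    CYP3A4: 0.45
    CYP3A5: 0.45
    CYP2D6: 0.70
  enterocyte_cyp3a4: 0.90
  albumin: 0.75
  hematocrit: 0.90
  gfr: 0.90
  hepatic_flow: 0.85
hi_cp_c:
  liver_size: 0.73
  enzyme:
    CYP3A4: 0.30
    CYP3A5: 0.30
    CYP2D6: 0.55
  enterocyte_cyp3a4: 0.85
  albumin: 0.60
  hematocrit: 0.85
  gfr: 0.75
  hepatic_flow: 0.75
ri_moderate:
  liver_size: 1.00
  enzyme:
    CYP3A4: 0.95
    CYP3A5: 0.95
    CYP2D6: 1.00
  enterocyte_cyp3a4: 1.00
  albumin: 0.96
  hematocrit: 0.92
  gfr: 0.41          # 105 -> ~43 mL/min (moderate band 30-60)
  hepatic_flow: 1.00
ri_severe:
  liver_size: 1.00
  enzyme:
    CYP3A4: 0.90
    CYP3A5: 0.90
    CYP2D6: 1.00
  enterocyte_cyp3a4: 1.00
  albumin: 0.93
  hematocrit: 0.88
  gfr: 0.18          # 105 -> ~19 mL/min (severe band < 30)
  hepatic_flow: 1.00
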