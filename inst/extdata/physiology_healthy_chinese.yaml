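# Mean physiology for a healthy adult Chinese virtual subject.
# Literature-typical values (open fixture); all simulations scale from this file.
name: healthy_chinese
body_weight: 61.6             # kg
cardiac_output: 312           # L/h
hematocrit: 0.43
albumin_scalar: 1.0           # 1 = healthy mean serum albumin
gfr: 105                      # mL/min
liver_weight: 1650            # g
mppgl: 42                     # mg microsomal protein / g liver
organ_volumes:                # L
  adipose: 10.0
  bone: 9.0
  brain: 1.40
  gut: 1.10
  heart: 0.33
  kidney: 0.28
  liver: 1.65
  lung: 0.50
  muscle: 26.0
  skin: 3.00
  spleen: 0.17
  pancreas: 0.10
  arterial_blood: 1.30
  venous_blood: 3.10
blood_flow_fractions:         # fraction of cardiac output on the arterial side; sums to 1
  adipose: 0.055
  bone: 0.050
  brain: 0.120
  gut: 0.160
  heart: 0.050
  kidney: 0.190
  liver: 0.070                # hepatic artery only; portal inflow adds gut+spleen+pancreas
  muscle: 0.200
  skin: 0.068
  spleen: 0.025
  pancreas: 0.012
enzyme_abundance:             # scalar on the in vitro Vmax (1 = healthy mean)
  CYP3A4: 1.0
  CYP3A5: 1.0
  CYP2D6: 1.0
enterocyte_cyp3a4_scalar: 1.0
clint_gut_cyp3a4: 0.90        # L/h unbound intrinsic clearance, whole small-intestinal wall
q_villi: 18                   # L/h mucosal blood flow opposing first-pass extraction
kdeg:                         # 1/h enzyme degradation constants
  liver_CYP3A4: 0.0193
  liver_CYP3A5: 0.0193
  liver_CYP2D6: 0.0099
  gut_CYP3A4: 0.030
gut_segments:                 # fasted-state geometry and transit
  names:        [stomach, duodenum, jejunum1, jejunum2, ileum1, ileum2, ileum3, caecum, colon]
  volume_ml:    [47, 12, 35, 35, 25, 25, 15, 10, 10]
  ph:           [1.5, 6.0, 6.2, 6.4, 6.8, 7.0, 7.2, 6.4, 6.8]
  transit_h:    [0.35, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 4.5, 13.5]
  radius_cm:    [10.0, 1.40, 1.30, 1.20, 1.10, 1.00, 0.90, 3.5, 2.5]
  peff_scalar:  [0.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.05, 0.02]
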