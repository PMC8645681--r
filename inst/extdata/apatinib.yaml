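# Victim-drug parameter file: apatinib (free base MW; mesylate dose handled by salt_factor)
name: apatinib
molecular_weight: 397.48      # g/mol
log_p: 3.14
compound_class: diprotic_base
pka1: 6.60
pka2: 5.31
fu_plasma: 0.076
blood_to_plasma: 0.995
papp_caco2: 6.81e-6           # cm/s, Caco-2 apical->basolateral
peff_calibration_factor: 11.7474   # single-point anchor: 0.80e-4 / 6.81e-6
peff_human: 0.80              # 1e-4 cm/s
kp_scalar: 0.7
vss_predicted: 2.684          # L/kg, reference value for the tissue-composition method
# Biopharmaceutics (calibrated surrogate for the unpublished tablet dissolution profile;
# see the methods vignette for the calibration procedure)
intrinsic_solubility: 0.18    # mg/mL, un-ionized species
solubility_cap: 1.0           # mg/mL, ceiling on pH-amplified luminal solubility
dissolution_coefficient: 1.2  # 1/h on a mg^(1/3) basis (rate = kd * M_solid^(2/3) * (1 - C/S))
salt_factor: 1.0              # labelled dose treated as free-base mass
fu_microsomes: 0.45           # nonspecific microsomal binding correction on Km (unbound Km = Km x fu_mic)
enzymes:
  CYP3A4: {vmax: 39.1, km: 2.18}   # pmol/min/mg microsomal protein; uM
  CYP3A5: {vmax: 3.28, km: 1.93}
  CYP2D6: {vmax: 9.82, km: 1.41}
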