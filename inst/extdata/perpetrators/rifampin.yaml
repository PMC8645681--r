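# Strong CYP3A4 inducer (weak competitive component); calibration fixture
name: rifampin
molecular_weight: 822.9
fu: 0.15
pk: {ka: 1.0, v_f: 55, cl_f: 7}
dosing: {dose_mg: 600, schedule: qd, days: 10}
interactions:
  CYP3A4: {ind_max: 8.0, ind_c50: 0.32, ki: 18}   # ind_c50 uM unbound
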