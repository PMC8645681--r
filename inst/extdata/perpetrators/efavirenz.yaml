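# Moderate CYP3A4 inducer; highly protein bound; calibration fixture
name: efavirenz
molecular_weight: 315.7
fu: 0.01
pk: {ka: 0.4, v_f: 250, cl_f: 9}
dosing: {dose_mg: 600, schedule: qd, days: 10}
interactions:
  CYP3A4: {ind_max: 3.0, ind_c50: 0.05}
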