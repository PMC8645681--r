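# CYP3A4 inducer (steady-state autoinduced clearance); calibration fixture
name: carbamazepine
molecular_weight: 236.3
fu: 0.25
pk: {ka: 0.5, v_f: 80, cl_f: 4}
dosing: {dose_mg: 400, schedule: bid, days: 10}
interactions:
  CYP3A4: {ind_max: 5.0, ind_c50: 7.0}
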