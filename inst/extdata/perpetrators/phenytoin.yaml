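# CYP3A4 inducer; calibration fixture
name: phenytoin
molecular_weight: 252.3
fu: 0.10
pk: {ka: 0.6, v_f: 45, cl_f: 1.5}
dosing: {dose_mg: 300, schedule: qd, days: 10}
interactions:
  CYP3A4: {ind_max: 4.5, ind_c50: 3.0}
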