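# Mechanism-based CYP2D6 inactivator; calibration fixture
name: paroxetine
molecular_weight: 329.4
fu: 0.05
pk: {ka: 0.5, v_f: 400, cl_f: 12.5}
dosing: {dose_mg: 30, schedule: qd, days: 6}
interactions:
  CYP2D6: {kinact: 2.0, k_i: 0.30}      # 1/h; uM unbound
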