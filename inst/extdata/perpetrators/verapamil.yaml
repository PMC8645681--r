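# Moderate CYP3A mechanism-based inactivator; calibration fixture
name: verapamil
molecular_weight: 454.6
fu: 0.10
pk: {ka: 1.0, v_f: 300, cl_f: 60}
dosing: {dose_mg: 120, schedule: tid, days: 6}
interactions:
  CYP3A4: {kinact: 1.2, k_i: 2.5}
  CYP3A5: {kinact: 1.2, k_i: 2.5}
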