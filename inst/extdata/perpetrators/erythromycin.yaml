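# Moderate CYP3A mechanism-based inactivator; calibration fixture
name: erythromycin
molecular_weight: 733.9
fu: 0.30
pk: {ka: 1.0, v_f: 300, cl_f: 105}
dosing: {dose_mg: 250, schedule: qid, days: 6}
interactions:
  CYP3A4: {kinact: 3.0, k_i: 4.0}
  CYP3A5: {kinact: 3.0, k_i: 4.0}
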