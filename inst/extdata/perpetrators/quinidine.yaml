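# Potent competitive CYP2D6 inhibitor; calibration fixture
name: quinidine
molecular_weight: 324.4
fu: 0.17
pk: {ka: 1.2, v_f: 160, cl_f: 15}
dosing: {dose_mg: 200, schedule: qd, days: 6}
interactions:
  CYP2D6: {ki: 0.10}
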