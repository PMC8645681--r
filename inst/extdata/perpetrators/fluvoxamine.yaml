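# Weak competitive CYP2D6 inhibitor at therapeutic exposure; calibration fixture
name: fluvoxamine
molecular_weight: 318.3
fu: 0.23
pk: {ka: 0.6, v_f: 1300, cl_f: 100}
dosing: {dose_mg: 50, schedule: qd, days: 6}
interactions:
  CYP2D6: {ki: 1.6}
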