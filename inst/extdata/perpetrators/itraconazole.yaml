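# Strong competitive CYP3A inhibitor; literature-typical constants (calibration fixture)
name: itraconazole
molecular_weight: 705.6
fu: 0.036
pk: {ka: 0.8, v_f: 700, cl_f: 22}       # one-compartment oral, apparent V and CL
dosing: {dose_mg: 100, schedule: qd, days: 6}
interactions:
  CYP3A4: {ki: 0.0013}                   # uM, unbound
  CYP3A5: {ki: 0.0013}
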