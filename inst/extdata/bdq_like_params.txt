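# parent-metabolite structural parameters; units: h, mg, L
MTT: 3.5  # h
NTR: 5  # count
KA: 0.69999999999999996  # 1/h
CL_P: 2.7999999999999998  # L/h
V1_P: 150  # L
V2_P: 771.6207871380609  # L
V3_P: 6566.5856005373953  # L
Q2_P: 40  # L/h
Q3_P: 2  # L/h
CL_M: 6  # L/h
V1_M: 300  # L
V2_M: 10741.760605558136  # L
Q_M: 3.7228105389962565  # L/h
F: 1  # fraction
fm: 1  # fraction
exp_CL: 0.75  # unitless
exp_V: 1  # unitless
WT_ref: 70  # kg
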