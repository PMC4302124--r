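name: E-T-C
protocol: ETC
cycle_length_days: 14
n_cycles: 9
risk_groups: [all]
applications:
- drug: epirubicin
  dose: "150 mg/m2, 3-h-Infusion"
  days: [1]
  cycles: [1, 2, 3]
  toxicity: E150
- drug: paclitaxel
  dose: "225 mg/m2, 3-h-Infusion"
  days: [1]
  cycles: [4, 5, 6]
  toxicity: P225
- drug: cyclophosphamide
  dose: "2500 mg/m2, 24-h-Infusion"
  days: [1]
  cycles: [7, 8, 9]
  toxicity: C2500
notes: >
  Sequential dose-dense epirubicin, paclitaxel, cyclophosphamide: three
  14-day cycles of each single drug.
external_knowledge_days: yes
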