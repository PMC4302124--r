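name: EC-T
protocol: EC-T
cycle_length_days: 21
n_cycles: 8
risk_groups: [all]
applications:
- drug: epirubicin
  dose: "90 mg/m2, 3-h-Infusion"
  days: [1]
  cycles: [1, 2, 3, 4]
  toxicity: E90
- drug: cyclophosphamide
  dose: "600 mg/m2, 24-h-Infusion"
  days: [1]
  cycles: [1, 2, 3, 4]
  toxicity: C600
- drug: paclitaxel
  dose: "175 mg/m2, 3-h-Infusion"
  days: [1]
  cycles: [5, 6, 7, 8]
  toxicity: P175
notes: >
  Four cycles of combined epirubicin/cyclophosphamide followed by four
  cycles of single-drug paclitaxel.
external_knowledge_days: yes
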