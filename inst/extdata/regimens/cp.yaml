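name: CP
protocol: Carboplatin+Paclitaxel
cycle_length_days: 21
n_cycles: 4
risk_groups: [all]
applications:
- drug: carboplatin+paclitaxel
  dose: "Carboplatin (variable), Paclitaxel 225 mg/m2"
  days: [1]
  toxicity: CP
notes: >
  Carboplatin plus paclitaxel for NSCLC; the combination carries a single
  joint toxicity set because it is less toxic than its components.
external_knowledge_days: yes
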