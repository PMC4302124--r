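name: TA
protocol: TA
cycle_length_days: 21
n_cycles: 4
risk_groups: [all]
applications:
- drug: doxorubicin+docetaxel
  dose: "Doxorubicin 60 mg/m2, Docetaxel 75 mg/m2"
  days: [1]
  toxicity: TA
notes: Adjuvant breast-cancer doxorubicin/docetaxel, 21-day cycles.
external_knowledge_days: yes
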