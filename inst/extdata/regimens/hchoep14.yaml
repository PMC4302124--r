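name: high-CHOEP-14
protocol: high-CHOEP
cycle_length_days: 14
n_cycles: 6
risk_groups: [all]
applications:
- drug: cyclophosphamide+doxorubicin+vincristine
  dose: "Cyclophosphamide 1400 mg/m2 d1, Doxorubicin 32.5 mg/m2/d d1-2, Vincristine 2 mg d1"
  days: [1]
  toxicity: CDh
- drug: etoposide
  dose: "175 mg/m2/d"
  days: [1, 2, 3]
  toxicity: ETh
- drug: prednisone
  dose: "100 mg"
  days: [1, 2, 3, 4, 5]
  cytotoxic: no
notes: >
  Dose-escalated CHOEP. The CDh toxicity set covers the cyclophosphamide,
  doxorubicin and vincristine combination; its pulse is placed on day 1.
external_knowledge_days: yes
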