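name: BEACOPP-21 escalated
protocol: BEACOPP escalated
cycle_length_days: 21
n_cycles: 8
risk_groups: [all]
applications:
- drug: cyclophosphamide+doxorubicin
  dose: "Cyclophosphamide 1250 mg/m2 d1, Doxorubicin 35 mg/m2 d1"
  days: [1]
  toxicity: CDesk
- drug: etoposide
  dose: "200 mg/m2/d"
  days: [1, 2, 3]
  toxicity: ETesk
- drug: procarbazine
  dose: "100 mg/m2/d"
  days: [1, 2, 3, 4, 5, 6, 7]
  toxicity: PROC
- drug: vincristine+bleomycin
  dose: "Vincristine 2 mg, Bleomycin 10 mg/m2"
  days: [8]
  toxicity: VB
- drug: prednisone
  dose: "100 mg"
  days: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14]
  cytotoxic: no
notes: Escalated BEACOPP, 21-day cycles.
external_knowledge_days: yes
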