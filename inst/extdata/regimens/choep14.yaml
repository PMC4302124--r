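name: CHOEP-14
protocol: CHOEP
cycle_length_days: 14
n_cycles: 6
risk_groups: [young, elderly]
applications:
- drug: cyclophosphamide+doxorubicin+vincristine
  dose: "Cyclophosphamide 750 mg/m2, Doxorubicin 50 mg/m2, Vincristine 2 mg"
  days: [1]
  toxicity: {young: CHOPy, elderly: CHOPo}
- drug: etoposide
  dose: "100 mg/m2/d"
  days: [1, 2, 3]
  toxicity: {young: ETy, elderly: ETo}
- drug: prednisone
  dose: "100 mg"
  days: [1, 2, 3, 4, 5]
  cytotoxic: no
notes: CHOP plus etoposide 100 mg/m2 on days 1-3, 14-day cycles.
external_knowledge_days: yes
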