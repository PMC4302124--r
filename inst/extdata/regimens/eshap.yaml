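name: ESHAP
protocol: ESHAP
cycle_length_days: 28
n_cycles: 4
risk_groups: [all]
applications:
- drug: etoposide
  dose: "40 mg/m2/d"
  days: [1, 2, 3, 4]
  toxicity: ET40
- drug: cisplatin
  dose: "25 mg/m2/d"
  days: [1, 2, 3, 4]
  toxicity: Cisp
- drug: cytarabine
  dose: "2000 mg/m2"
  days: [5]
  toxicity: Cyta
- drug: methylprednisolone
  dose: "500 mg"
  days: [1, 2, 3, 4, 5]
  cytotoxic: no
notes: >
  Salvage therapy for relapsed/persistent lymphoma. Methylprednisolone is
  treated as prednisone-like (non-cytotoxic). Cycle length and within-cycle
  days are standard protocol knowledge.
external_knowledge_days: yes
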