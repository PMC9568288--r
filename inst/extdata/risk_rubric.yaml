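# Default additive risk rubric for peri-implant disease.
# Nine scored parameters; each level carries a risk percentage contribution.
# Total risk = sum of the nine per-parameter percentages (maximum 100.0).
parameters:
- name: periodontal_history_compliance
  label: Previous periodontal history and compliance to therapy
  levels:
  - score: 0
    descriptor: History absent, compliant with therapy
    percentage: 0.0
  - score: 1
    descriptor: History absent, noncompliant with therapy
    percentage: 2.5
  - score: 2
    descriptor: History present, compliant with therapy
    percentage: 7.5
  - score: 3
    descriptor: History present, noncompliant with therapy
    percentage: 12.5
- name: plaque_status
  label: Plaque status (modified plaque index)
  levels:
  - score: 0
    descriptor: No detection of plaque
    percentage: 0.0
  - score: 1
    descriptor: Plaque only recognized by running a probe across the smooth
      marginal surface of the implant
    percentage: 2.5
  - score: 2
    descriptor: Plaque can be seen by naked eye
    percentage: 5.0
  - score: 3
    descriptor: Abundance of soft matter
    percentage: 7.5
- name: gingival_status
  label: Gingival status (modified gingival index)
  levels:
  - score: 0
    descriptor: No bleeding on probing
    percentage: 0.0
  - score: 1
    descriptor: Isolated bleeding spots visible
    percentage: 2.5
  - score: 2
    descriptor: Blood forms a confluent red line on the margin
    percentage: 5.0
  - score: 3
    descriptor: Heavy or profuse bleeding
    percentage: 7.5
- name: diabetes
  label: Diabetes status, random blood glucose (mg/dl)
  levels:
  - score: 0
    descriptor: Below 102
    percentage: 0.0
  - score: 1
    descriptor: 102 to 109
    percentage: 2.5
  - score: 2
    descriptor: 110 to 117
    percentage: 5.0
  - score: 3
    descriptor: 118 to 125
    percentage: 7.5
  - score: 4
    descriptor: 126 to 133
    percentage: 10.0
  - score: 5
    descriptor: Above 133
    percentage: 12.5
- name: smoking
  label: Smoking status (cigarettes/day)
  levels:
  - score: 0
    descriptor: Nonsmoker
    percentage: 0.0
  - score: 1
    descriptor: Former smoker
    percentage: 2.5
  - score: 2
    descriptor: Current, fewer than 10 per day
    percentage: 5.0
  - score: 3
    descriptor: Current, 10 to 19 per day
    percentage: 7.5
  - score: 4
    descriptor: Current, 20 per day
    percentage: 10.0
  - score: 5
    descriptor: Current, more than 20 per day
    percentage: 12.5
- name: residual_cement
  label: Residual cement
  levels:
  - score: 0
    descriptor: Absent
    percentage: 0.0
  - score: 1
    descriptor: Present
    percentage: 12.5
- name: occlusal_overload
  label: Occlusal overload (wear facet and/or premature contact)
  levels:
  - score: 0
    descriptor: Absent
    percentage: 0.0
  - score: 1
    descriptor: Present
    percentage: 12.5
- name: keratinized_width
  label: Width of keratinized mucosa
  levels:
  - score: 0
    descriptor: Sufficient (2 mm or more)
    percentage: 0.0
  - score: 1
    descriptor: Insufficient (less than 2 mm)
    percentage: 12.5
- name: other_alcohol
  label: Other potential risk factors (alcohol consumption)
  levels:
  - score: 0
    descriptor: Absent
    percentage: 0.0
  - score: 1
    descriptor: Present
    percentage: 10.0
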