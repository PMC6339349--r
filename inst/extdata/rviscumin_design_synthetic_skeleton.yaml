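# Two-stage likelihood-based CRM design of the rViscumin trial in solid
# tumours. The trial's actual skeleton was specified after the first DLT and
# was never published: the skeleton below is SYNTHETIC (a plausible
# hand-specified curve with the prior MTD guess at level 11), so this
# fixture exercises the two-stage machinery without reproducing the trial's
# numeric estimates.
panel:
  doses: [10, 20, 40, 100, 200, 400, 800, 1600, 2400, 3200, 4000, 4800, 5600, 6400]
  unit: ng/kg
skeleton: [0.02, 0.03, 0.04, 0.05, 0.07, 0.09, 0.11, 0.13, 0.15, 0.18, 0.20, 0.24, 0.28, 0.33]
model:
  family: power
  slope_link: exp
ttl: 0.20
cohort_size: 1
max_n: 40
decision_rule: closest_to_ttl
safety:
  no_skipping: yes
  enforce_coherence: no
  start_dose: 1
stopping:
- kind: next_m_same_dose
  m: 5
  prob: 0.9
stage1:
  cohort_size: 1
  expand_on_moderate: yes
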