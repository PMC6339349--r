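# Bayesian CRM design of the ssHHT dose-finding trial in advanced AML.
# Dose labels are built at the prior median of the slope; with the plug-in
# central-estimate convention this reproduces the trial's published
# posterior DLT-probability estimates to two decimals.
panel:
  doses: [0.5, 1.0, 3.0, 5.0, 6.0]
  unit: mg/m^2/day
skeleton: [0.05, 0.10, 0.15, 0.33, 0.50]
model:
  family: logistic1
  intercept: 3.0
  slope_link: identity
prior:
  family: exponential
  rate: 1.0
  central: median
ttl: 0.33
cohort_size: 3
max_n: 18
decision_rule: closest_to_ttl
safety:
  no_skipping: no
  enforce_coherence: no
  start_dose: 1
stopping:
- kind: mtd_estimate_change
  delta: 0.05
  quantifier: worst_case
convention: plugin_at_posterior_mean
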