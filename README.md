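# crmdose

Design, conduct and evaluation of phase I dose-finding trials with the
**continual reassessment method (CRM)**.

Phase I trials look for the maximum tolerated dose (MTD): the dose whose
probability of a dose-limiting toxicity (DLT) equals a pre-specified target
toxicity level (TTL). Most trials still use the rule-based 3+3 design, which
ignores the TTL and uses only the current dose's data. The CRM instead fits a
monotone dose-toxicity model

F(β, d) — e.g. the power model d^exp(β) or the one-parameter logistic
logit⁻¹(3 + exp(β)·d)

to *all* accrued data after every cohort and assigns the dose whose estimated
DLT probability is closest to the TTL. Doses enter on a working scale of
*labels* d_i solving F(β\*, d_i) = p_i for the clinicians' prior skeleton
p_1 < … < p_k at the prior central value β\*, so the model matches the
clinical prior exactly before any data accrue.

The package is aimed at trial statisticians who need to specify, simulate,
document and run such a design. It provides:

* the three standard dose-toxicity families with analytic skeleton-to-label
  inversion, skeleton validation, and Lee–Cheung indifference-interval
  skeleton calibration;
* Bayesian inference by deterministic quadrature (exponential, normal or
  lognormal priors; plug-in and posterior-mean-of-probability estimate
  conventions; credible intervals; posterior tail probabilities for safety
  rules) and two-stage maximum-likelihood inference with profile-likelihood
  intervals;
* trial conduct: decision rules (closest to TTL / closest without
  exceeding), safety constraints (no dose skipping, coherence, start dose),
  and stopping rules (sample size, consecutive-at-dose, excessive toxicity,
  interval width, next-m-patients-same-dose, MTD-estimate stability),
  composed by `next_cohort()`;
* exact operating characteristics of the 3+3 by full path enumeration, a
  nonparametric complete-tolerance-profile benchmark, and Monte-Carlo
  operating characteristics of any design across scenario suites with
  common random numbers;
* exhaustive dose-transition-pathway enumeration for committee reports,
  the next-m stopping rule, and coherence audits;
* YAML design files, per-patient CSV data files, interim and simulation
  reports, a thin command-line wrapper (`inst/cli/crm.R`), and replays of
  two published CRM trials as fixtures.

## Worked example: replaying the ssHHT trial

The packaged fixture is the Bayesian CRM trial of semi-synthetic
homoharringtonine in advanced acute myeloid leukaemia: five doses (0.5, 1,
3, 5, 6 mg/m²/day), TTL 0.33, one-parameter logistic model with intercept 3,
an exponential prior with mean 1 on the positive slope, and skeleton
(0.05, 0.10, 0.15, 0.33, 0.50).

```r
library(crmdose)
design <- sshht_design()

state <- trial_state(design)
state <- record_cohort(state, dose_index = 1, dlts = 0)   # 0/3 DLTs
next_cohort(state)
#> Next cohort: dose level 5 (3 patients) — model recommendation

# the investigators overrode the jump to the top dose and treated at dose 3
state <- record_cohort(state, dose_index = 3, dlts = 1, note = "committee override")
next_cohort(state)
#> Next cohort: dose level 4 (3 patients) — model recommendation

for (i in 1:4) state <- record_cohort(state, 4, 1)        # 4/12 DLTs at dose 4
interim_report(state)
#> Interim report: 18 patients treated (TTL 0.33, plugin_at_posterior_mean)
#>  dose actual_dose       unit  n dlt estimate lower upper
#>     1         0.5 mg/m^2/day  3   0    0.060 0.011 0.220
#>     2         1.0 mg/m^2/day  0   0    0.116 0.029 0.325
#>     3         3.0 mg/m^2/day  3   1    0.170 0.050 0.402
#>     4         5.0 mg/m^2/day 12   4    0.356 0.160 0.584
#>     5         6.0 mg/m^2/day  0   0    0.523 0.317 0.700
#> STOP: max_n - maximum sample size (18) reached
```

After no DLTs in the first cohort the model recommends the largest dose; one
DLT among the override cohort pulls the recommendation to 5 mg/m²/day; after
18 patients the estimated DLT probabilities are 0.06–0.52 across the panel,
dose 4 (estimate 0.356, the value closest to the TTL of 0.33) is the MTD,
and the trial stops. The estimate column reproduces the trial's published
posterior estimates to two decimals; dose labels are built at the prior
median of the slope, the convention recorded in the fixture.

Pre-trial evaluation against the 3+3 and the benchmark:

```r
suite <- scenario_suite(design$skeleton, ttl = 0.33)        # k + 2 scenarios
cmp <- compare_designs(list(crm = design,
                            p3  = three_plus_three_design(5)),
                       suite, replications = 2000, seed = 20260919)
write_simulation_report(simulation_report(cmp, design, seed = 20260919), "oc_report")
```

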