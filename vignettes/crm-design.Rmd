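---
title: "Designing dose-finding trials with the continual reassessment method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dose-finding trials with the continual reassessment method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmdose)
```

## The problem and the model

A phase I dose-escalation trial looks for the maximum tolerated dose (MTD):
the dose whose probability of causing a dose-limiting toxicity (DLT) equals
a pre-specified target toxicity level (TTL), typically 20–35%. The
continual reassessment method (CRM) treats this as a sequential estimation
problem. A one-parameter dose-toxicity function $F(\beta, d)$, strictly
increasing in the working-scale dose $d$, is re-estimated after every
cohort, and the next cohort receives the dose whose estimated DLT
probability best matches the TTL.

`crmdose` implements three standard families:

* power (empiric): $F(\beta, d) = d^{\exp(\beta)}$, $d \in (0,1)$;
* one-parameter logistic: $F(\beta, d) = \text{logit}^{-1}(c + \exp(\beta)\,d)$
  with fixed intercept $c$ (default 3);
* two-parameter logistic: $F(\boldsymbol\beta, d) =
  \text{logit}^{-1}(\beta_1 + \exp(\beta_2)\,d)$.

The slope can alternatively enter untransformed as a positive parameter
$a > 0$ (`slope_link = "identity"`), the natural pairing with
positive-support priors such as an exponential prior. Both
parameterisations appear in published trials and both are supported.

### Skeleton and dose labels

Clinicians provide a *skeleton* $p_1 < \dots < p_k$ of prior DLT
probabilities. The actual doses (mg, ng/kg, …) never enter the model;
instead each dose receives a *label* $d_i$ solving $F(\beta^*, d_i) = p_i$
at a central parameter value $\beta^*$, so the model reproduces the
clinical prior exactly before any data accrue. The inversion is analytic
for all three families (`dose_labels()`), and the package checks the
round-trip to $10^{-10}$.

$\beta^*$ may be the prior mean or the prior median; both are legitimate
and published trials are rarely explicit about which was used. Both are
supported through the prior's `central` setting. For the packaged ssHHT
replay (below) the labels are built at the **prior median**: that is the
convention under which the replay reproduces the trial's published
posterior estimates to two decimals, and it is recorded in the fixture
itself. With an Exp(1) prior the two choices differ materially
($\beta^* = 1$ versus $\ln 2$), which is a useful reminder that the
convention is part of the design and belongs in the protocol.

### Skeleton calibration

When no prior data support a hand-specified skeleton,
`skeleton_from_indifference()` generates one from the TTL $\theta$ and an
indifference half-width $\delta$: the skeleton value at the prior MTD guess
is set to $\theta$, and neighbours are solved outward so that at the
parameter value where one dose sits at $\theta \mp \delta$ its neighbour
sits at $\theta \pm \delta$ — consecutive doses' indifference intervals
tile the probability scale. A TTL of 25% with $\delta = 5$% yields the
indifference interval [20%, 30%].

The recursion contracts quickly: on long panels (say 12–14 levels) the
skeleton values far below the prior MTD guess underflow toward zero, which
is why the packaged 14-level two-stage fixture uses a plausible
hand-specified synthetic skeleton instead of a calibrated one.
`validate_skeleton()` flags adjacent gaps below 0.02 (escalation will be
slow) or above 0.30 (convergence will be poor); the thresholds are
advisory — the literature warns qualitatively and offers no sharp number.

## Inference

### Bayesian updating by quadrature

With per-dose tallies $(n_i, y_i)$ the likelihood is a product of
binomials in $F(\beta, d_i)$. The posterior over $\beta$ is computed by
deterministic quadrature: a uniform grid of 2001 points spanning all but
$10^{-12}$ of prior mass per tail, trapezoidal integration, and all
likelihood work in log space. At phase I sample sizes the posterior is
smooth and unimodal on this grid; estimates are converged to about eight
significant digits (doubling the grid changes nothing at $10^{-8}$), and
the suite asserts normalisation to $10^{-6}$ and agreement with a
$10^6$-draw importance-sampling oracle within three Monte-Carlo standard
errors. The two-parameter family runs the same contract on a
$401 \times 401$ tensor grid over each prior's $(10^{-9}, 1-10^{-9})$
quantile range.

Two central-estimate conventions exist in practice and both are
implemented: plug the posterior mean of $\beta$ into $F$
(`plugin_at_posterior_mean`, the default) or average $F(\beta, d_i)$ over
the posterior (`posterior_mean_of_prob`). They typically differ by a few
percentage points early in a trial; published reports rarely say which was
used, so `posterior_estimates()` records its convention in the output and
interim reports echo it. Interval bounds are always percentiles of the
induced per-dose probability distribution (2.5th/97.5th at the default
95% level), matching how trial reports present credible intervals.

### Two-stage maximum likelihood

The binomial likelihood has no interior maximum until the data contain at
least one DLT and one non-DLT, so likelihood-based designs run in two
stages. Stage 1 escalates single patients (or small cohorts) through the
panel by rule; a moderate (grade 2+, non-DLT) toxicity expands the current
dose to three patients, and escalation continues only if none of the three
has a DLT. The first DLT switches to model-based conduct with *all*
stage-1 data entering the likelihood. `mle_estimates()` raises an explicit
heterogeneity error before the switch, which is the signal the engine uses
to stay in stage 1. The skeleton may be supplied only at the switch
(`set_skeleton()`), as happened in the rViscumin trial.

MLE confidence bounds invert the likelihood-ratio statistic on the
parameter (profile likelihood) and map through the monotone $F$, which
respects $[0,1]$ by construction; the two-parameter family falls back to a
Wald interval on the logit scale, flagged in the `ci_method` attribute.

## Conduct: decision, safety, stopping

Two decision rules are provided: *closest to the TTL* (fast escalation)
and *closest without exceeding the TTL* (conservative). Ties go to the
lower dose — the conservative resolution. When every estimate exceeds the
TTL, the conservative rule recommends dose 1 and relies on an
excessive-toxicity stopping rule; this degenerate case has no established
convention and the package's choice keeps the rule total.

Safety modifications compose after the decision rule: no skipping of
untested levels when escalating, optional coherence enforcement (never a
higher dose immediately after a cohort with a DLT), and a configured start
dose. Coherence is typically guaranteed by the CRM itself, but the package
can audit it (`coherence_audit()`) by exhaustively enumerating the
dose-transition-pathway tree and scanning for an escalation following a
DLT-containing cohort.

Stopping rules are evaluated in configured order after each complete
cohort, first hit wins, and the design's maximum sample size is always
enforced as a final implicit rule. The rule "stop when adding another
cohort would not change the estimate of the DLT probability at the MTD by
more than $\delta$" needs a quantifier over the unknown next-cohort
outcome, which published descriptions leave implicit. The package offers
two readings: `worst_case` (the default — the maximum change over all
possible DLT counts, the only branch-free reading) and `expected` (the
posterior-predictive average of the absolute change). In the ssHHT replay
the worst-case measure is still 0.097 after 18 patients while the expected
measure falls below 0.05 from 15 patients on, for every admissible
within-dose ordering of the recorded DLTs — so neither reading first fires
at exactly the recorded 18. The packaged fixture therefore sets the
design's maximum at the trial's realised 18 patients (the only sample-size
anchor the published account provides) and keeps the change rule
configured with its worst-case default; the replay then terminates at 18
through the sample-size rule. Users replicating their own trials should
pre-register the quantifier.

The rule "stop when the next $m$ patients are certain to receive one
dose" is evaluated by pathway enumeration: `prob_next_m_same()` sums the
posterior-predictive probabilities of the outcome branches on which every
one of the next $m$ assignments equals the current recommendation, and
returns exactly 1 when that holds on every branch. The stopping rule and
the user-facing function share one code path. Branches on which the trial
stops before $m$ further patients count toward the stable set (no
divergent dosing can occur on them); the rule's own firing is excluded
from the enumeration, since it would otherwise recurse.

## Dose transition pathways

`enumerate_pathways()` computes, before the data exist, every feasible
dose sequence over the next few cohorts. Branches are indexed by DLT
*count* per cohort — within-cohort orderings are exchangeable under the
binomial likelihood, so collapsing $2^c$ orderings to $c+1$ counts is
lossless. Every node's recommendation is recomputed from its cumulative
data through the full engine (inference, decision, safety, stopping), so
the tree is exactly what the trial would do. A guard refuses trees beyond
$10^6$ nodes. `pathway_table()` renders the tree one row per path for
dose-setting-committee reports.

## Comparators

The 3+3 design is implemented twice, deliberately: an exact enumeration of
all reachable paths with binomial branch probabilities
(`three_plus_three_exact_oc()`) and an independent vectorised Monte-Carlo
simulator; the suite requires them to agree within three binomial standard
errors. One dialect point is not covered by the classical description,
which only defines termination by toxicity: when escalation exhausts the
panel without two DLTs at the top dose, the package declares the top dose
the MTD — the common complete-path convention, noted here because other
software sometimes reports "all doses tolerable" as a distinct outcome.

The nonparametric benchmark gives each simulated patient a latent
tolerance $u \sim U(0,1)$ and evaluates their DLT status at *every* dose
($u \le p_i$), as if each patient could be observed at all doses; each
dose's toxicity rate is estimated from these complete profiles and the
dose closest to the TTL selected. No implementable design has more
information, so the benchmark's accuracy bounds what any design can
achieve at the same sample size.

## Simulation

`simulate_trials()` draws cohort outcomes as independent Bernoulli
variables at the assigned dose's true probability and runs the full engine
to its stop. The scenario generator covers the recommended suite: one
scenario per dose placing the TTL exactly there (power-transforming the
skeleton, $p_j^{\log\theta/\log p_i}$, which preserves monotonicity), plus
the two extremes in which the lowest dose is already above the MTD or the
highest still below it. Operating characteristics reported per scenario:
MTD-selection distribution (including "none"), per-dose allocation, DLT
counts, sample-size distribution, and study duration under a pluggable
accrual stub (a fixed interval per cohort, default one unit — the
literature lists duration as an operating characteristic but prescribes no
accrual model, so anything richer belongs to the user).

Design comparisons use common random numbers: replication $r$ gets the
same sub-seed for every design, which removes between-design Monte-Carlo
noise from paired contrasts. Every result records its seed and replication
count, and identical seeds reproduce results bitwise. The default of
2,000 replications keeps selection-probability standard errors near one
percentage point; the package's own test suite uses 20–4,000 replications
depending on what the assertion needs, with the largest runs reserved for
the exact-versus-simulated 3+3 cross-check ($10^4$) and the
importance-sampling oracle ($10^6$ draws).

What the Bernoulli outcome model does *not* emulate: late-onset
toxicities and partial observation (TITE-style weighting), toxicity
grades beyond the binary DLT plus the stage-1 moderate flag,
patient-level covariates or cohort heterogeneity, and accrual-time
randomness. Passing simulations therefore demonstrate the decision
machinery under the design's own assumptions, not robustness to violations
of them.

## Case-study fixtures

Two published trials ship as fixtures. The ssHHT trial in advanced acute
myeloid leukaemia (Bayesian, one-parameter logistic with intercept 3,
Exp(1) prior on the positive slope, skeleton 0.05/0.10/0.15/0.33/0.50, TTL
0.33, three-patient cohorts, no no-skipping constraint) is replayed in the
acceptance suite: cohort one (0/3 DLTs at the lowest dose) drives the
model's recommendation to the top dose, the investigators' recorded
override places cohort two at dose 3, one DLT there brings the
recommendation to dose 4, and after 18 patients the per-dose estimates
reproduce the published 0.06 / 0.12 / 0.17 / 0.36 / 0.53 within ±0.01 with
dose 4 declared MTD. The published account gives per-dose totals only, so
the fixture spreads the four dose-4 DLTs one per cohort; inference is
exchangeable within dose, so this affects only path-dependent quantities
(stopping-rule trajectories), not the final estimates.

The rViscumin trial in solid tumours exercises the two-stage machinery:
single-patient stage-1 escalation over a 14-level panel, moderate-toxicity
expansion, the switch at the first DLT, and a stop when the next five
patients are certain to receive one dose. Its true skeleton was specified
mid-trial and never published, so the fixture's skeleton is synthetic
(clearly labelled in the file and accessor) and the trial's numeric
estimates are out of reach by construction.

## Numerical choices, in one place

* Quadrature: 2001-point uniform grid over the $(10^{-12}, 1-10^{-12})$
  prior quantile range; trapezoidal rule; log-space likelihood;
  $401^2$ grid for the two-parameter family.
* Label inversion: analytic; round-trip asserted to $10^{-10}$.
* MLE: golden-section/`optimize()` on the bounded parameter range
  ($\beta \in [-15, 15]$ for the exponential link, $a \in [10^{-8}, 100]$
  for the identity link); profile-likelihood intervals by root-finding at
  $10^{-9}$ tolerance.
* Ties in `which.min` resolve to the lower dose everywhere.
* Degenerate inputs: skeletons on the (0,1) boundary, non-monotone
  skeletons and non-positive panels are hard errors; empty data are valid
  for Bayesian inference and an explicit heterogeneity error for MLE.

## Known limitations

Binary DLT endpoint only; no time-to-event weighting, grade-severity
models, efficacy-toxicity trade-offs, combinations, schedules or
covariates. The indifference-interval calibration degenerates on very long
panels. Study duration uses the fixed-interval accrual stub. The
two-parameter logistic is provided for completeness but phase I sample
sizes rarely identify both parameters well; its confidence intervals fall
back to Wald approximations.
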