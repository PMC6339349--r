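#' Dose-escalation decision rule
#'
#' Two decision rules are in common use: assign the dose whose estimated
#' DLT probability is closest to the TTL (fast escalation towards the MTD),
#' or, more conservatively, closest to but not greater than the TTL. Ties at
#' equidistant doses go to the lower dose.
#'
#' @param kind `"closest_to_ttl"` or `"closest_not_exceeding"`.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(kind = c("closest_to_ttl", "closest_not_exceeding")) {
  structure(list(kind = match.arg(kind), tie_break = "lower_dose"),
            class = "decision_rule")
}

#' Safety constraints on dose escalation
#'
#' @param no_skipping Never escalate past the next untested dose level.
#' @param enforce_coherence If the most recent cohort contained a DLT, do
#'   not assign a dose above that cohort's dose, even if the model
#'   recommends it.
#' @param start_dose Dose level for the first cohort (commonly at or below
#'   the prior MTD guess, often the lowest dose).
#' @return An object of class `safety_rules`.
#' @export
safety_rules <- function(no_skipping = TRUE, enforce_coherence = FALSE,
                         start_dose = 1L) {
  structure(list(no_skipping = isTRUE(no_skipping),
                 enforce_coherence = isTRUE(enforce_coherence),
                 start_dose = as.integer(start_dose)),
            class = "safety_rules")
}

# ---- stopping rules -------------------------------------------------------

new_stopping_rule <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "stopping_rule")
}

#' Stopping rules
#'
#' Constructors for the stopping criteria a CRM design can combine, checked
#' in configured order after each complete cohort (first firing rule wins):
#'
#' * `stop_max_n(n)` — maximum sample size reached (always also enforced
#'   from the design's `max_n`);
#' * `stop_consecutive_at_dose(n)` — `n` consecutive patients dosed at one
#'   level;
#' * `stop_all_doses_toxic(margin, prob)` — the posterior probability that
#'   the lowest dose's DLT risk exceeds TTL + `margin` is above `prob`
#'   (the Viola trial used margin 0.10 and prob 0.72); Bayesian designs
#'   only;
#' * `stop_interval_width(level, max_width)` — the credible/confidence
#'   interval at the current MTD estimate is narrower than `max_width`;
#' * `stop_next_m_same(m, prob)` — the probability that the next `m`
#'   patients will all receive the same dose, whatever their outcomes,
#'   exceeds `prob` (evaluated by dose-transition-pathway enumeration);
#' * `stop_mtd_change(delta, quantifier)` — adding one more cohort could not
#'   (`"worst_case"`) or is not expected to (`"expected"`, posterior
#'   predictive weighting) change the DLT-probability estimate at the
#'   current MTD by more than `delta`.
#'
#' @param n,m Positive integer counts.
#' @param margin,prob,delta,max_width Probabilities in (0, 1).
#' @param level Interval level for `stop_interval_width`.
#' @param quantifier How to aggregate over next-cohort outcomes for
#'   `stop_mtd_change`.
#' @return An object of class `stopping_rule`.
#' @name stopping_rules
NULL

#' @rdname stopping_rules
#' @export
stop_max_n <- function(n) new_stopping_rule("max_n", n = as.integer(n))

#' @rdname stopping_rules
#' @export
stop_consecutive_at_dose <- function(n)
  new_stopping_rule("consecutive_at_dose", n = as.integer(n))

#' @rdname stopping_rules
#' @export
stop_all_doses_toxic <- function(margin = 0.1, prob = 0.9)
  new_stopping_rule("all_doses_toxic", margin = margin, prob = prob)

#' @rdname stopping_rules
#' @export
stop_interval_width <- function(level = 0.95, max_width)
  new_stopping_rule("interval_width", level = level, max_width = max_width)

#' @rdname stopping_rules
#' @export
stop_next_m_same <- function(m, prob = 0.9)
  new_stopping_rule("next_m_same_dose", m = as.integer(m), prob = prob)

#' @rdname stopping_rules
#' @export
stop_mtd_change <- function(delta = 0.05,
                            quantifier = c("worst_case", "expected"))
  new_stopping_rule("mtd_estimate_change", delta = delta,
                    quantifier = match.arg(quantifier))

# ---- design ---------------------------------------------------------------

#' Assemble a CRM trial design
#'
#' Bundles every design choice — dose panel, skeleton, dose-toxicity model,
#' prior, TTL, cohort and sample sizes, decision, safety and stopping
#' rules — into the immutable object the conduct, simulation and pathway
#' functions operate on.
#'
#' Bayesian one-stage designs supply a `prior`; two-stage likelihood designs
#' supply a `stage1` configuration (see [stage1_config()]) instead, and may
#' defer the skeleton until the model-based stage starts (as done in the
#' rViscumin trial, where the skeleton was specified after the first DLT).
#'
#' @param panel A [dose_panel()].
#' @param skeleton Prior DLT probabilities (may be `NULL` for a two-stage
#'   design until the stage switch).
#' @param model A [crm_model()].
#' @param ttl Target toxicity level in (0, 1).
#' @param prior A [crm_prior()] (or list of two for `logistic2`), `NULL` for
#'   likelihood-based designs.
#' @param cohort_size Patients per model-based cohort.
#' @param max_n Maximum number of patients.
#' @param decision A [decision_rule()].
#' @param safety A [safety_rules()].
#' @param stopping List of [stopping_rules] evaluated in order.
#' @param stage1 A [stage1_config()] for two-stage designs, else `NULL`.
#' @param convention Central-estimate convention passed to
#'   [posterior_estimates()].
#' @return An object of class `crm_design`.
#' @export
crm_design <- function(panel, skeleton, model, ttl, prior = NULL,
                       cohort_size = 3L, max_n,
                       decision = decision_rule("closest_to_ttl"),
                       safety = safety_rules(), stopping = list(),
                       stage1 = NULL,
                       convention = c("plugin_at_posterior_mean",
                                      "posterior_mean_of_prob")) {
  stopifnot(inherits(panel, "dose_panel"), inherits(model, "crm_model"),
            inherits(decision, "decision_rule"),
            inherits(safety, "safety_rules"))
  convention <- match.arg(convention)
  stopifnot(is.numeric(ttl), length(ttl) == 1L, ttl > 0, ttl < 1)
  cohort_size <- as.integer(cohort_size)
  max_n <- as.integer(max_n)
  stopifnot(cohort_size >= 1L, max_n >= cohort_size)
  if (!is.null(stage1) && !inherits(stage1, "stage1_config"))
    stop("'stage1' must come from stage1_config()", call. = FALSE)
  method <- if (!is.null(prior)) "bayes" else "likelihood"
  if (method == "likelihood" && is.null(stage1))
    stop("a likelihood-based design needs a stage1_config(): maximum ",
         "likelihood requires heterogeneous data, obtained by rule-based ",
         "stage-1 escalation", call. = FALSE)
  if (method == "likelihood") {
    bayes_only <- vapply(stopping, function(r)
      r$kind == "all_doses_toxic", logical(1))
    if (any(bayes_only))
      stop("stop_all_doses_toxic() needs Bayesian machinery; ",
           "it cannot be combined with a pure-likelihood design",
           call. = FALSE)
  }
  if (!all(vapply(stopping, inherits, logical(1), "stopping_rule")))
    stop("'stopping' must be a list of stopping rules", call. = FALSE)
  if (safety$start_dose < 1L || safety$start_dose > panel$k)
    stop("start dose outside the panel", call. = FALSE)

  labels <- NULL
  if (!is.null(skeleton)) {
    assert_skeleton(skeleton)
    if (length(skeleton) != panel$k)
      stop("skeleton length must equal the number of dose levels",
           call. = FALSE)
    labels <- dose_labels(model, skeleton, design_central_param(model, prior))
  }
  structure(list(panel = panel, skeleton = skeleton, model = model,
                 prior = prior, ttl = ttl, cohort_size = cohort_size,
                 max_n = max_n, decision = decision, safety = safety,
                 stopping = stopping, stage1 = stage1, method = method,
                 convention = convention, labels = labels),
            class = "crm_design")
}

# beta* used for label construction: the prior central value for Bayesian
# designs; for likelihood designs the Table-style reference (effective
# slope 1).
design_central_param <- function(model, prior) {
  if (is.null(prior)) {
    ref <- if (model$slope_link == "exp") 0 else 1
    if (model$n_params == 2L) c(0, ref) else ref
  } else if (model$n_params == 2L) {
    vapply(prior, prior_central, numeric(1))
  } else prior_central(prior)
}

#' Supply the skeleton of a two-stage design at the stage switch
#'
#' @param design A [crm_design()] built without a skeleton.
#' @param skeleton The skeleton to adopt.
#' @return The updated design.
#' @export
set_skeleton <- function(design, skeleton) {
  stopifnot(inherits(design, "crm_design"))
  assert_skeleton(skeleton)
  if (length(skeleton) != design$panel$k)
    stop("skeleton length must equal the number of dose levels", call. = FALSE)
  design$skeleton <- skeleton
  design$labels <- dose_labels(design$model, skeleton,
                               design_central_param(design$model, design$prior))
  design
}

#' Stage-1 configuration for a two-stage design
#'
#' Rule-based escalation used until the first DLT: single patients (or small
#' cohorts) walk up the panel; a moderate (grade 2+, non-DLT) toxicity
#' expands the current dose to three patients, and escalation continues only
#' if none of the three has a DLT. The first DLT switches the trial to the
#' model-based stage, with all stage-1 data entering the likelihood.
#'
#' @param cohort_size Patients per stage-1 step (1 in the rViscumin trial).
#' @param expand_on_moderate Whether a moderate-toxicity event triggers the
#'   three-patient expansion.
#' @return An object of class `stage1_config`.
#' @export
stage1_config <- function(cohort_size = 1L, expand_on_moderate = TRUE) {
  structure(list(cohort_size = as.integer(cohort_size),
                 expand_on_moderate = isTRUE(expand_on_moderate)),
            class = "stage1_config")
}

#' @export
print.crm_design <- function(x, ...) {
  cat(sprintf("CRM design: %d doses (%s %s), TTL %.2f, %s inference\n",
              x$panel$k, paste(x$panel$doses, collapse = "/"), x$panel$unit,
              x$ttl, x$method))
  if (!is.null(x$skeleton))
    cat("  skeleton:", paste(format(x$skeleton), collapse = ", "), "\n")
  cat(sprintf("  cohort size %d, max n %d, decision rule %s\n",
              x$cohort_size, x$max_n, x$decision$kind))
  invisible(x)
}

# ---- trial state ----------------------------------------------------------

#' Trial state
#'
#' The accrued per-patient records together with the design. The stage is
#' derived from the records: a two-stage design is in stage 1 until the
#' first DLT is observed.
#'
#' @param design A [crm_design()].
#' @param records Patient records from [patient_records()] (default empty).
#' @return An object of class `trial_state`.
#' @export
trial_state <- function(design, records = NULL) {
  stopifnot(inherits(design, "crm_design"))
  if (is.null(records)) records <- patient_records(integer(), integer())
  if (nrow(records) > design$max_n)
    stop("more records than the design's maximum sample size", call. = FALSE)
  dose_tallies(records, design$panel$k)  # validates dose indices
  structure(list(design = design, records = records, log = list()),
            class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  tal <- dose_tallies(x$records, x$design$panel$k)
  cat(sprintf("Trial state: %d patients, %d DLTs, stage: %s\n",
              nrow(x$records), sum(tal$y), trial_stage(x)))
  invisible(x)
}

#' Current stage of a trial
#'
#' @param state A [trial_state()].
#' @return `"stage1"` or `"model_based"`.
#' @export
trial_stage <- function(state) {
  if (is.null(state$design$stage1)) return("model_based")
  if (nrow(state$records) > 0L && any(state$records$dlt == 1L))
    "model_based" else "stage1"
}

#' Record a completed cohort
#'
#' Appends one cohort's outcomes to the trial state and logs the event. The
#' dose actually given may differ from the model's recommendation (a
#' dose-setting-committee override); pass `note` to record why.
#'
#' @param state A [trial_state()].
#' @param dose_index Dose level given to the cohort.
#' @param dlts Number of DLTs observed in the cohort.
#' @param n_patients Cohort size (defaults to the design's cohort size).
#' @param moderate Number of patients with moderate (non-DLT) toxicity.
#' @param note Optional free-text annotation (e.g. an override reason).
#' @return The updated `trial_state`.
#' @export
record_cohort <- function(state, dose_index, dlts,
                          n_patients = state$design$cohort_size,
                          moderate = 0L, note = NULL) {
  stopifnot(inherits(state, "trial_state"))
  k <- state$design$panel$k
  dose_index <- as.integer(dose_index)
  stopifnot(dose_index >= 1L, dose_index <= k, dlts >= 0L,
            dlts <= n_patients, moderate >= 0L, moderate <= n_patients)
  n0 <- nrow(state$records)
  if (n0 + n_patients > state$design$max_n)
    stop("cohort would exceed the design's maximum sample size", call. = FALSE)
  cid <- if (n0 == 0L) 1L else max(state$records$cohort_id) + 1L
  dlt_vec <- c(rep(1L, dlts), rep(0L, n_patients - dlts))
  mod_vec <- c(rep(1L, moderate), rep(0L, n_patients - moderate))
  new <- data.frame(patient_id = n0 + seq_len(n_patients),
                    dose_index = dose_index, dlt = dlt_vec,
                    moderate_tox = mod_vec, cohort_id = cid)
  state$records <- rbind(state$records, new)
  state$log <- c(state$log, list(list(
    event = "cohort", cohort_id = cid, dose_index = dose_index,
    n = n_patients, dlts = as.integer(dlts), note = note,
    timestamp = Sys.time())))
  state
}

# Per-dose estimates under the design's inference method. Errors with the
# heterogeneity message in likelihood mode before the first DLT.
state_estimates <- function(state, interval_level = 0.95) {
  d <- state$design
  if (is.null(d$labels))
    stop("skeleton missing: supply it with set_skeleton() before the ",
         "model-based stage", call. = FALSE)
  if (d$method == "bayes")
    posterior_estimates(d$model, d$labels, d$prior, state$records,
                        interval_level = interval_level,
                        convention = d$convention)
  else
    mle_estimates(d$model, d$labels, state$records,
                  interval_level = interval_level)
}

# ---- decision, safety, stopping ------------------------------------------

#' Model-based dose recommendation
#'
#' Applies a decision rule to per-dose estimates: `closest_to_ttl` returns
#' the dose minimising the absolute distance of the estimated DLT
#' probability from the TTL (ties to the lower dose); `closest_not_exceeding`
#' returns the highest dose whose estimate does not exceed the TTL, or dose
#' 1 if every estimate exceeds it (in which case an excessive-toxicity
#' stopping rule should be in force).
#'
#' @param estimates A `tox_estimates` table (or any data frame with an
#'   `estimate` column ordered by dose).
#' @param ttl Target toxicity level.
#' @param rule A [decision_rule()].
#' @return The recommended dose index.
#' @export
recommend <- function(estimates, ttl, rule = decision_rule("closest_to_ttl")) {
  est <- estimates$estimate
  stopifnot(length(est) >= 1L)
  if (rule$kind == "closest_to_ttl") {
    which.min(abs(est - ttl))  # first minimum = lower dose on ties
  } else {
    ok <- which(est <= ttl)
    if (length(ok) == 0L) 1L else max(ok)
  }
}

#' Apply safety constraints to a recommendation
#'
#' @param recommended Unconstrained model recommendation (dose index).
#' @param state A [trial_state()].
#' @param rules A [safety_rules()] (defaults to the design's).
#' @return The constrained dose index.
#' @export
apply_safety <- function(recommended, state, rules = state$design$safety) {
  if (nrow(state$records) == 0L) return(rules$start_dose)
  dose <- recommended
  if (rules$no_skipping) {
    highest <- max(state$records$dose_index)
    dose <- min(dose, highest + 1L)
  }
  if (rules$enforce_coherence) {
    last_cohort <- state$records[state$records$cohort_id ==
                                   max(state$records$cohort_id), ]
    if (any(last_cohort$dlt == 1L))
      dose <- min(dose, last_cohort$dose_index[1L])
  }
  as.integer(min(max(dose, 1L), state$design$panel$k))
}

# Posterior-predictive distribution of the DLT count in a cohort of size c
# at dose index i (Bayesian), or plug-in binomial at the MLE (likelihood).
predictive_dlt_dist <- function(state, dose_index, c_size) {
  d <- state$design
  if (d$method == "bayes") {
    fit <- posterior_fit(d$model, d$labels, d$prior, state$records)
    pm <- if (fit$n_params == 1L) matrix(fit$grid, ncol = 1L) else fit$grid
    p <- exp(.log_prob_dlt(d$model, pm, d$labels[dose_index])[, 1L])
    vapply(0:c_size, function(j)
      posterior_expect(fit, function(g) stats::dbinom(j, c_size, p)),
      numeric(1))
  } else {
    est <- mle_estimates(d$model, d$labels, state$records)
    stats::dbinom(0:c_size, c_size, est$estimate[dose_index])
  }
}

eval_stopping_rule <- function(rule, state, est = NULL) {
  d <- state$design
  n <- nrow(state$records)
  fired <- FALSE
  reason <- NULL
  switch(rule$kind,
    max_n = {
      if (n >= rule$n) {
        fired <- TRUE
        reason <- sprintf("maximum sample size (%d) reached", rule$n)
      }
    },
    consecutive_at_dose = {
      if (n >= rule$n &&
          length(unique(utils::tail(state$records$dose_index, rule$n))) == 1L) {
        fired <- TRUE
        reason <- sprintf("%d consecutive patients at dose %d", rule$n,
                          utils::tail(state$records$dose_index, 1L))
      }
    },
    all_doses_toxic = {
      if (d$method != "bayes")
        stop("stop_all_doses_toxic() requires Bayesian inference",
             call. = FALSE)
      pt <- posterior_tail(d$model, d$labels, d$prior, state$records,
                           dose_index = 1L, threshold = d$ttl + rule$margin)
      if (pt > rule$prob) {
        fired <- TRUE
        reason <- sprintf(
          "P(DLT risk at lowest dose > TTL + %.2f) = %.3f exceeds %.2f",
          rule$margin, pt, rule$prob)
      }
    },
    interval_width = {
      e <- state_estimates(state, interval_level = rule$level)
      mtd <- recommend(e, d$ttl, d$decision)
      width <- e$upper[mtd] - e$lower[mtd]
      if (width <= rule$max_width) {
        fired <- TRUE
        reason <- sprintf("interval width %.3f at MTD estimate (dose %d) <= %.3f",
                          width, mtd, rule$max_width)
      }
    },
    next_m_same_dose = {
      pr <- prob_next_m_same(state, rule$m)
      if (pr >= rule$prob) {
        fired <- TRUE
        reason <- sprintf("P(next %d patients at one dose) = %.3f >= %.2f",
                          rule$m, pr, rule$prob)
      }
    },
    mtd_estimate_change = {
      if (is.null(est)) est <- state_estimates(state)
      mtd <- recommend(est, d$ttl, d$decision)
      next_dose <- apply_safety(recommend(est, d$ttl, d$decision), state)
      base <- est$estimate[mtd]
      changes <- vapply(0:d$cohort_size, function(j) {
        s2 <- record_cohort_unchecked(state, next_dose, j, d$cohort_size)
        abs(state_estimates(s2)$estimate[mtd] - base)
      }, numeric(1))
      measure <- if (rule$quantifier == "worst_case") max(changes) else
        sum(changes * predictive_dlt_dist(state, next_dose, d$cohort_size))
      if (measure <= rule$delta) {
        fired <- TRUE
        reason <- sprintf(
          "%s change in MTD estimate from one more cohort = %.4f <= %.2f",
          rule$quantifier, measure, rule$delta)
      }
    },
    stop(sprintf("unknown stopping rule kind '%s'", rule$kind), call. = FALSE)
  )
  if (fired) list(rule = rule$kind, reason = reason) else NULL
}

# record_cohort without the max_n guard, for hypothetical-outcome branches.
record_cohort_unchecked <- function(state, dose_index, dlts, n_patients) {
  state$design$max_n <- state$design$max_n + n_patients
  record_cohort(state, dose_index, dlts, n_patients)
}

#' Evaluate the design's stopping rules
#'
#' Rules are checked in configured order after each complete cohort; the
#' first rule that fires wins. The design's maximum sample size is always
#' enforced (as a final implicit `max_n` rule if not listed).
#'
#' @param state A [trial_state()].
#' @param rules List of stopping rules (defaults to the design's).
#' @return `NULL` to continue, else a list with elements `rule` and
#'   `reason`.
#' @export
check_stopping <- function(state, rules = state$design$stopping) {
  if (!any(vapply(rules, function(r) r$kind == "max_n", logical(1))))
    rules <- c(rules, list(stop_max_n(state$design$max_n)))
  if (trial_stage(state) == "stage1") {
    # model-based criteria have nothing to evaluate before the stage switch
    rules <- Filter(function(r)
      r$kind %in% c("max_n", "consecutive_at_dose"), rules)
  }
  for (r in rules) {
    hit <- eval_stopping_rule(r, state)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# ---- conduct --------------------------------------------------------------

# Stage-1 rule-based assignment derived statelessly from the records.
# Returns list(dose, n_patients) or a stop marker when the panel is
# exhausted without a DLT.
stage1_assignment <- function(state) {
  d <- state$design
  s1 <- d$stage1
  rec <- state$records
  if (nrow(rec) == 0L)
    return(list(dose = d$safety$start_dose, n = s1$cohort_size))
  d_last <- utils::tail(rec$dose_index, 1L)
  at_last <- rec[rec$dose_index == d_last, ]
  if (s1$expand_on_moderate && any(at_last$moderate_tox == 1L) &&
      nrow(at_last) < 3L)
    return(list(dose = d_last, n = 3L - nrow(at_last)))
  if (d_last >= d$panel$k)
    return(list(stop = list(rule = "stage1_exhausted",
                            reason = "panel exhausted without a DLT")))
  list(dose = d_last + 1L, n = s1$cohort_size)
}

#' Recommend the next cohort's dose
#'
#' Composes the full per-cohort decision: evaluate stopping rules, update
#' the per-dose estimates, apply the decision rule, then the safety
#' constraints. In stage 1 of a two-stage design the rule-based escalation
#' is applied instead of the model.
#'
#' @param state A [trial_state()] whose previous cohort is complete.
#' @return An object of class `crm_recommendation`: a list with
#'   `dose_index` (NA when stopping), `unconstrained_dose_index`,
#'   `n_patients`, `reason`, `stop` (NULL or the fired rule) and, in the
#'   model-based stage, the `estimates` table.
#' @export
next_cohort <- function(state) {
  stopifnot(inherits(state, "trial_state"))
  d <- state$design
  if (nrow(state$records) == 0L) {
    n1 <- if (trial_stage(state) == "stage1") d$stage1$cohort_size else
      d$cohort_size
    return(structure(list(dose_index = d$safety$start_dose,
                          unconstrained_dose_index = d$safety$start_dose,
                          n_patients = n1, reason = "first cohort",
                          stop = NULL, estimates = NULL),
                     class = "crm_recommendation"))
  }
  stop_hit <- check_stopping(state)
  if (!is.null(stop_hit))
    return(structure(list(dose_index = NA_integer_,
                          unconstrained_dose_index = NA_integer_,
                          n_patients = 0L, reason = stop_hit$reason,
                          stop = stop_hit, estimates = NULL),
                     class = "crm_recommendation"))
  if (trial_stage(state) == "stage1") {
    a <- stage1_assignment(state)
    if (!is.null(a$stop))
      return(structure(list(dose_index = NA_integer_,
                            unconstrained_dose_index = NA_integer_,
                            n_patients = 0L, reason = a$stop$reason,
                            stop = a$stop, estimates = NULL),
                       class = "crm_recommendation"))
    return(structure(list(dose_index = a$dose,
                          unconstrained_dose_index = a$dose,
                          n_patients = min(a$n, d$max_n - nrow(state$records)),
                          reason = "stage-1 escalation",
                          stop = NULL, estimates = NULL),
                     class = "crm_recommendation"))
  }
  est <- state_estimates(state)
  unc <- recommend(est, d$ttl, d$decision)
  dose <- apply_safety(unc, state)
  # never treat more patients than max_n allows
  n_pat <- min(d$cohort_size, d$max_n - nrow(state$records))
  structure(list(dose_index = dose, unconstrained_dose_index = unc,
                 n_patients = n_pat,
                 reason = if (dose < unc)
                   "model recommendation capped by safety rules" else
                     "model recommendation",
                 stop = NULL, estimates = est),
            class = "crm_recommendation")
}

#' @export
print.crm_recommendation <- function(x, ...) {
  if (!is.null(x$stop)) {
    cat("STOP:", x$stop$rule, "-", x$reason, "\n")
  } else {
    cat(sprintf("Next cohort: dose level %d (%d patient%s) — %s\n",
                x$dose_index, x$n_patients,
                if (x$n_patients == 1L) "" else "s", x$reason))
  }
  invisible(x)
}

#' Run a complete trial against a response oracle
#'
#' Conducts a trial from an empty state to a stop decision, drawing each
#' patient's outcome from `response_oracle(patient_index, dose_index)`,
#' which must return a list with binary elements `dlt` and (optionally)
#' `moderate`. Handles both one-stage Bayesian and two-stage likelihood
#' designs; [run_two_stage()] is the documented entry point for the latter.
#'
#' @param design A [crm_design()].
#' @param response_oracle Function mapping `(patient, dose)` to outcomes.
#' @return A list with the final `state`, the declared `mtd` (dose index or
#'   `NA`), final `estimates` (or NULL if never model-fitted), `stop` (the
#'   fired rule) and `n_cohorts`.
#' @export
run_crm_trial <- function(design, response_oracle) {
  state <- trial_state(design)
  n_cohorts <- 0L
  stop_hit <- NULL
  repeat {
    rec <- next_cohort(state)
    if (!is.null(rec$stop)) { stop_hit <- rec$stop; break }
    outs <- lapply(seq_len(rec$n_patients), function(j)
      response_oracle(nrow(state$records) + j, rec$dose_index))
    dlts <- sum(vapply(outs, function(o) as.integer(o$dlt), integer(1)))
    mods <- sum(vapply(outs, function(o)
      as.integer(o$moderate %||% 0L), integer(1)))
    state <- record_cohort(state, rec$dose_index, dlts,
                           n_patients = rec$n_patients, moderate = mods)
    n_cohorts <- n_cohorts + 1L
  }
  est <- NULL
  mtd <- NA_integer_
  can_estimate <- !is.null(state$design$labels) &&
    (state$design$method == "bayes" ||
       (sum(state$records$dlt) > 0L &&
          sum(state$records$dlt) < nrow(state$records)))
  if (can_estimate && nrow(state$records) > 0L) {
    est <- state_estimates(state)
    mtd <- recommend(est, design$ttl, design$decision)
  }
  list(state = state, mtd = mtd, estimates = est, stop = stop_hit,
       n_cohorts = n_cohorts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a two-stage likelihood-based trial
#'
#' Stage 1 escalates single patients (or small cohorts) through the panel,
#' expanding to three patients on a moderate non-DLT toxicity; the first DLT
#' switches to model-based conduct with all stage-1 data entering the
#' likelihood.
#'
#' @inheritParams run_crm_trial
#' @return See [run_crm_trial()].
#' @export
run_two_stage <- function(design, response_oracle) {
  stopifnot(inherits(design, "crm_design"))
  if (is.null(design$stage1))
    stop("run_two_stage() needs a design with a stage1_config()",
         call. = FALSE)
  run_crm_trial(design, response_oracle)
}
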