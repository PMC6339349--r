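# Shared builders for unit tests. All fixtures are constructed in code.

# Small Bayesian design: power model, normal prior on beta (exp slope link),
# labels at the prior mean (= 0), so empty-data plug-in estimates equal the
# skeleton.
tiny_design <- function(k = 3, ttl = 0.25, max_n = 9, cohort_size = 3,
                        skeleton = NULL, stopping = list(),
                        safety = safety_rules(no_skipping = TRUE),
                        convention = "plugin_at_posterior_mean") {
  if (is.null(skeleton))
    skeleton <- seq(0.1, 0.4, length.out = k)
  crm_design(
    panel = dose_panel(seq_len(k) * 10, "mg"),
    skeleton = skeleton,
    model = crm_model("power", slope_link = "exp"),
    prior = crm_prior("normal", mean = 0, sd = 1, central = "mean"),
    ttl = ttl, cohort_size = cohort_size, max_n = max_n,
    safety = safety, stopping = stopping, convention = convention)
}

# The ssHHT case-study design built in code (identical to the packaged
# fixture).
sshht_design_code <- function(max_n = 18) {
  crm_design(
    panel = dose_panel(c(0.5, 1, 3, 5, 6), "mg/m^2/day"),
    skeleton = c(0.05, 0.10, 0.15, 0.33, 0.50),
    model = crm_model("logistic1", intercept = 3, slope_link = "identity"),
    prior = crm_prior("exponential", rate = 1, central = "median"),
    ttl = 0.33, cohort_size = 3, max_n = max_n,
    safety = safety_rules(no_skipping = FALSE, start_dose = 1),
    stopping = list(stop_mtd_change(0.05, "worst_case")),
    convention = "plugin_at_posterior_mean")
}

# ssHHT recorded data as cohort totals (DLT ordering at dose 4 is the
# fixture convention: one DLT per cohort).
sshht_records <- function() {
  patient_records(
    dose_index = c(rep(1, 3), rep(3, 3), rep(4, 12)),
    dlt = c(0, 0, 0, 1, 0, 0, rep(c(1, 0, 0), 4)),
    cohort_id = rep(1:6, each = 3))
}

# Importance-sampling Monte-Carlo oracle for the posterior mean of the
# per-dose DLT probability, independent of the quadrature path. Returns the
# estimates and their Monte-Carlo standard errors.
mc_posterior_oracle <- function(model, labels, prior, data, draws = 1e5) {
  k <- length(labels)
  tal <- crmdose:::dose_tallies(data, k)
  if (model$n_params == 1L) {
    th <- crmdose:::prior_sample(prior, draws)
    pm <- matrix(th, ncol = 1)
  } else {
    th1 <- crmdose:::prior_sample(prior[[1]], draws)
    th2 <- crmdose:::prior_sample(prior[[2]], draws)
    pm <- cbind(th1, th2)
  }
  ll <- numeric(draws)
  for (i in which(tal$n > 0)) {
    l2 <- crmdose:::.log_prob_dlt(model, pm, labels[i])
    ll <- ll + tal$y[i] * l2[, 1] + (tal$n[i] - tal$y[i]) * l2[, 2]
  }
  w <- exp(ll - max(ll))
  sw <- sum(w)
  est <- se <- numeric(k)
  for (i in seq_len(k)) {
    f <- exp(crmdose:::.log_prob_dlt(model, pm, labels[i])[, 1])
    mu <- sum(w * f) / sw
    se[i] <- sqrt(sum((w / sw)^2 * (f - mu)^2))
    est[i] <- mu
  }
  list(estimate = est, se = se)
}

# Random small heterogeneous-ish dataset on a k-dose panel.
random_small_data <- function(k, max_patients = 6) {
  n <- sample(1:max_patients, 1)
  patient_records(dose_index = sample(seq_len(k), n, replace = TRUE),
                  dlt = stats::rbinom(n, 1, 0.3))
}
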