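test_that("with no data, plug-in estimates at the prior central value equal the skeleton", {
  d <- tiny_design(k = 4)
  est <- posterior_estimates(d$model, d$labels, d$prior,
                             patient_records(integer(), integer()),
                             convention = "plugin_at_posterior_mean")
  expect_equal(est$estimate, d$skeleton, tolerance = 1e-6)
  expect_true(all(est$lower <= est$upper))
  expect_true(all(est$estimate >= 0 & est$estimate <= 1))
})

test_that("the posterior density is normalised on the quadrature grid", {
  d <- sshht_design_code()
  fit <- crmdose:::posterior_fit(d$model, d$labels, d$prior, sshht_records())
  expect_lt(abs(crmdose:::posterior_expect(fit, function(g) 1) - 1), 1e-6)
  # empty data too
  fit0 <- crmdose:::posterior_fit(d$model, d$labels, d$prior,
                                  patient_records(integer(), integer()))
  expect_lt(abs(crmdose:::posterior_expect(fit0, function(g) 1) - 1), 1e-6)
})

test_that("quadrature matches an importance-sampling oracle on small datasets", {
  set.seed(11)
  d <- sshht_design_code()
  for (i in 1:8) {
    dat <- random_small_data(5)
    est <- posterior_estimates(d$model, d$labels, d$prior, dat,
                               convention = "posterior_mean_of_prob")
    orc <- mc_posterior_oracle(d$model, d$labels, d$prior, dat, draws = 2e5)
    expect_true(all(abs(est$estimate - orc$estimate) <=
                      pmax(3 * orc$se, 1e-4)),
                label = sprintf("dataset %d", i))
  }
})

test_that("two-parameter posteriors follow the same contract", {
  m <- crm_model("logistic2", slope_link = "exp")
  pr <- list(crm_prior("normal", mean = 0, sd = 1),
             crm_prior("normal", mean = 0, sd = 1))
  skel <- c(0.1, 0.25, 0.4)
  lab <- dose_labels(m, skel, c(0, 0))
  dat <- patient_records(c(1, 1, 2, 2, 3), c(0, 0, 0, 1, 1))
  est <- posterior_estimates(m, lab, pr, dat,
                             convention = "posterior_mean_of_prob")
  expect_true(all(diff(est$estimate) > 0))
  orc <- mc_posterior_oracle(m, lab, pr, dat, draws = 2e5)
  expect_true(all(abs(est$estimate - orc$estimate) <= 3 * orc$se + 2e-3))
})

test_that("a DLT raises and a non-DLT lowers every dose's estimate", {
  d <- sshht_design_code(max_n = 30)
  base_dat <- sshht_records()
  base <- posterior_estimates(d$model, d$labels, d$prior, base_dat)$estimate
  for (dose in c(1, 3, 5)) {
    up <- rbind(base_dat, data.frame(patient_id = 19, dose_index = dose,
                                     dlt = 1L, moderate_tox = 0L,
                                     cohort_id = 7L))
    dn <- up; dn$dlt[19] <- 0L
    est_up <- posterior_estimates(d$model, d$labels, d$prior, up)$estimate
    est_dn <- posterior_estimates(d$model, d$labels, d$prior, dn)$estimate
    expect_true(all(est_up >= base - 1e-12))
    expect_true(all(est_dn <= base + 1e-12))
  }
})

test_that("posterior_tail respects support bounds and central mass", {
  d <- sshht_design_code()
  none <- patient_records(integer(), integer())
  expect_equal(posterior_tail(d$model, d$labels, d$prior, none, 2, 0), 1)
  expect_equal(posterior_tail(d$model, d$labels, d$prior, none, 2, 1), 0)
  # threshold at the skeleton value: prior splits the mass
  pt <- posterior_tail(d$model, d$labels, d$prior, none, 4, d$skeleton[4])
  expect_gt(pt, 0.2); expect_lt(pt, 0.8)
  # oracle cross-check on a small dataset
  set.seed(5)
  dat <- random_small_data(5)
  got <- posterior_tail(d$model, d$labels, d$prior, dat, 1, 0.3)
  th <- crmdose:::prior_sample(d$prior, 2e5)
  pm <- matrix(th, ncol = 1)
  tal <- crmdose:::dose_tallies(dat, 5)
  ll <- 0
  for (i in which(tal$n > 0)) {
    l2 <- crmdose:::.log_prob_dlt(d$model, pm, d$labels[i])
    ll <- ll + tal$y[i] * l2[, 1] + (tal$n[i] - tal$y[i]) * l2[, 2]
  }
  w <- exp(ll - max(ll)); w <- w / sum(w)
  f1 <- exp(crmdose:::.log_prob_dlt(d$model, pm, d$labels[1])[, 1])
  mu <- sum(w * (f1 > 0.3))
  se <- sqrt(sum(w^2 * ((f1 > 0.3) - mu)^2))
  expect_lt(abs(got - mu), 3 * se + 1e-3)
})

test_that("the two central-estimate conventions agree to 0.05 on the case study", {
  d <- sshht_design_code()
  dat <- sshht_records()
  plug <- posterior_estimates(d$model, d$labels, d$prior, dat,
                              convention = "plugin_at_posterior_mean")
  pmp <- posterior_estimates(d$model, d$labels, d$prior, dat,
                             convention = "posterior_mean_of_prob")
  expect_lt(max(abs(plug$estimate - pmp$estimate)), 0.05)
})

test_that("maximum likelihood requires heterogeneous data", {
  d <- tiny_design(k = 3)
  allzero <- patient_records(c(1, 2, 3), c(0, 0, 0))
  expect_error(mle_estimates(d$model, d$labels, allzero), "heterogeneity")
  allone <- patient_records(c(1, 2), c(1, 1))
  expect_error(mle_estimates(d$model, d$labels, allone), "heterogeneity")
})

test_that("the one-parameter MLE matches a grid search", {
  d <- tiny_design(k = 3)
  dat <- patient_records(c(1, 1, 2, 2, 3, 3), c(0, 0, 0, 1, 1, 1))
  est <- mle_estimates(d$model, d$labels, dat)
  ll <- crmdose:::loglik_fun(d$model, d$labels, crmdose:::dose_tallies(dat, 3))
  grid <- seq(-5, 5, by = 1e-4)
  gmax <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_lt(abs(attr(est, "param_summary")$mle - gmax), 1e-3)
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
})

test_that("one DLT and one non-DLT at a single dose gives an MLE of one half there", {
  d <- tiny_design(k = 3)
  dat <- patient_records(c(2, 2), c(1, 0))
  est <- mle_estimates(d$model, d$labels, dat)
  expect_equal(est$estimate[2], 0.5, tolerance = 1e-5)
})
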