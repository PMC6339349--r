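#' Prior specification for a model parameter
#'
#' One prior per model parameter. Positive-support priors (exponential,
#' lognormal) pair with the identity slope link, where the slope itself must
#' be positive; the normal prior pairs with the unconstrained
#' \eqn{\exp(\beta)} link (or with the `logistic2` intercept).
#'
#' @param family `"exponential"`, `"normal"` or `"lognormal"`.
#' @param rate Rate of the exponential prior (mean `1/rate`).
#' @param mean,sd Mean and standard deviation of the normal prior.
#' @param meanlog,sdlog Log-scale parameters of the lognormal prior.
#' @param central Which central value serves as \eqn{\beta^*} for the dose
#'   labels: `"mean"` or `"median"`.
#' @return An object of class `crm_prior`.
#' @examples
#' crm_prior("exponential", rate = 1, central = "median")
#' @export
crm_prior <- function(family = c("exponential", "normal", "lognormal"),
                      rate = 1, mean = 0, sd = 1, meanlog = 0, sdlog = 1,
                      central = c("mean", "median")) {
  family <- match.arg(family)
  central <- match.arg(central)
  pars <- switch(family,
    exponential = { stopifnot(rate > 0); list(rate = rate) },
    normal = { stopifnot(sd > 0); list(mean = mean, sd = sd) },
    lognormal = { stopifnot(sdlog > 0); list(meanlog = meanlog, sdlog = sdlog) }
  )
  structure(list(family = family, pars = pars, central = central),
            class = "crm_prior")
}

#' @export
print.crm_prior <- function(x, ...) {
  cat(sprintf("Prior: %s(%s), central value: %s = %g\n", x$family,
              paste(sprintf("%s=%g", names(x$pars), unlist(x$pars)),
                    collapse = ", "),
              x$central, prior_central(x)))
  invisible(x)
}

prior_positive_support <- function(prior) {
  prior$family %in% c("exponential", "lognormal")
}

#' Central value of a prior
#'
#' The prior mean or median, per the prior's `central` setting; this is the
#' \eqn{\beta^*} at which dose labels are constructed.
#'
#' @param prior A [crm_prior()].
#' @return A single number.
#' @export
prior_central <- function(prior) {
  stopifnot(inherits(prior, "crm_prior"))
  p <- prior$pars
  switch(prior$family,
    exponential = if (prior$central == "mean") 1 / p$rate else
      stats::qexp(0.5, p$rate),
    normal = p$mean,
    lognormal = if (prior$central == "mean")
      exp(p$meanlog + p$sdlog^2 / 2) else exp(p$meanlog)
  )
}

prior_logdens <- function(prior, x) {
  p <- prior$pars
  switch(prior$family,
    exponential = stats::dexp(x, p$rate, log = TRUE),
    normal = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    lognormal = stats::dlnorm(x, p$meanlog, p$sdlog, log = TRUE)
  )
}

prior_quantile <- function(prior, q) {
  p <- prior$pars
  switch(prior$family,
    exponential = stats::qexp(q, p$rate),
    normal = stats::qnorm(q, p$mean, p$sd),
    lognormal = stats::qlnorm(q, p$meanlog, p$sdlog)
  )
}

prior_sample <- function(prior, n) {
  p <- prior$pars
  switch(prior$family,
    exponential = stats::rexp(n, p$rate),
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog)
  )
}

#' Per-patient trial records
#'
#' Builds (and validates) the accrued-data table the inference and engine
#' functions consume: one row per patient.
#'
#' @param dose_index Integer vector of assigned dose levels (1..k).
#' @param dlt Binary vector of DLT outcomes.
#' @param moderate_tox Optional binary vector of moderate (grade 2+,
#'   non-DLT) toxicity flags used by the stage-1 escalation rule; defaults
#'   to 0.
#' @param cohort_id Optional cohort identifiers; defaults to one cohort per
#'   contiguous run of equal `dose_index`.
#' @param patient_id Optional patient identifiers; defaults to 1..n.
#' @return A `data.frame` with columns `patient_id`, `dose_index`, `dlt`,
#'   `moderate_tox`, `cohort_id`.
#' @examples
#' patient_records(dose_index = c(1, 1, 1, 3, 3, 3), dlt = c(0, 0, 0, 1, 0, 0))
#' @export
patient_records <- function(dose_index, dlt, moderate_tox = NULL,
                            cohort_id = NULL, patient_id = NULL) {
  n <- length(dose_index)
  stopifnot(length(dlt) == n)
  if (!all(dlt %in% c(0, 1)))
    stop("'dlt' must be binary (0/1)", call. = FALSE)
  if (is.null(moderate_tox)) moderate_tox <- rep(0L, n)
  if (!all(moderate_tox %in% c(0, 1)))
    stop("'moderate_tox' must be binary (0/1)", call. = FALSE)
  if (is.null(patient_id)) patient_id <- seq_len(n)
  if (is.null(cohort_id)) {
    cohort_id <- if (n == 0L) integer() else
      cumsum(c(1L, as.integer(diff(as.integer(dose_index)) != 0L)))
  }
  data.frame(patient_id = patient_id,
             dose_index = as.integer(dose_index),
             dlt = as.integer(dlt),
             moderate_tox = as.integer(moderate_tox),
             cohort_id = cohort_id)
}

# Per-dose (n, DLT) tallies; inference treats cohort outcomes as
# exchangeable, so the tallies are sufficient.
dose_tallies <- function(data, k) {
  if (is.null(data) || nrow(data) == 0L)
    return(list(n = integer(k), y = integer(k)))
  if (any(data$dose_index < 1L | data$dose_index > k))
    stop("dose_index outside the panel", call. = FALSE)
  list(n = tabulate(data$dose_index, k),
       y = tabulate(data$dose_index[data$dlt == 1L], k))
}

# ---- posterior quadrature -------------------------------------------------

# Deterministic quadrature grid covering all but ~1e-12 of prior mass per
# tail; the trapezoidal rule on this grid is converged to ~8 significant
# digits for the sample sizes a phase I trial can reach.
.posterior_grid_points <- 2001L

trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

# Posterior over the parameter(s) of a CRM model by quadrature of
# prior x binomial likelihood. Returns grid(s), normalised weights (which
# integrate to 1 against the grid), and parameter summaries.
posterior_fit <- function(model, labels, prior, data,
                          n_grid = .posterior_grid_points) {
  k <- length(labels)
  tal <- dose_tallies(data, k)
  if (model$n_params == 1L) {
    stopifnot(inherits(prior, "crm_prior"))
    if (model$slope_link == "identity" && !prior_positive_support(prior))
      stop("identity slope link requires a positive-support prior",
           call. = FALSE)
    g <- seq(prior_quantile(prior, 1e-12), prior_quantile(prior, 1 - 1e-12),
             length.out = n_grid)
    lp <- prior_logdens(prior, g)
    pm <- matrix(g, ncol = 1L)
    for (i in which(tal$n > 0L)) {
      l2 <- .log_prob_dlt(model, pm, labels[i])
      lp <- lp + tal$y[i] * l2[, 1L] + (tal$n[i] - tal$y[i]) * l2[, 2L]
    }
    m <- max(lp)
    w <- exp(lp - m)
    z <- trapz(g, w)
    if (!is.finite(z) || z <= 0)
      stop("posterior quadrature failed to normalise; check the data and prior",
           call. = FALSE)
    w <- w / z
    cdf <- cumsum(c(0, diff(g) * (w[-1L] + w[-n_grid]) / 2))
    post_mean <- trapz(g, g * w)
    post_median <- stats::approx(cdf, g, xout = 0.5, ties = "ordered")$y
    structure(list(model = model, labels = labels, grid = g, w = w,
                   cdf = cdf, post_mean = post_mean,
                   post_median = post_median, tallies = tal,
                   n_params = 1L),
              class = "crm_posterior")
  } else {
    # logistic2: tensor-product grid, prior = list(intercept, slope) priors.
    if (!(is.list(prior) && length(prior) == 2L &&
          all(vapply(prior, inherits, TRUE, "crm_prior"))))
      stop("a two-parameter model needs a list of two priors", call. = FALSE)
    if (model$slope_link == "identity" && !prior_positive_support(prior[[2L]]))
      stop("identity slope link requires a positive-support prior on the slope",
           call. = FALSE)
    n2 <- .posterior_grid_2d
    g1 <- seq(prior_quantile(prior[[1L]], 1e-9),
              prior_quantile(prior[[1L]], 1 - 1e-9), length.out = n2)
    g2 <- seq(prior_quantile(prior[[2L]], 1e-9),
              prior_quantile(prior[[2L]], 1 - 1e-9), length.out = n2)
    gg <- expand.grid(b1 = g1, b2 = g2)
    lp <- prior_logdens(prior[[1L]], gg$b1) + prior_logdens(prior[[2L]], gg$b2)
    pm <- cbind(gg$b1, gg$b2)
    for (i in which(tal$n > 0L)) {
      l2 <- .log_prob_dlt(model, pm, labels[i])
      lp <- lp + tal$y[i] * l2[, 1L] + (tal$n[i] - tal$y[i]) * l2[, 2L]
    }
    w <- exp(lp - max(lp))
    h1 <- g1[2L] - g1[1L]; h2 <- g2[2L] - g2[1L]
    z <- sum(w) * h1 * h2
    w <- w / z
    structure(list(model = model, labels = labels, grid = pm, w = w,
                   cell = h1 * h2,
                   post_mean = c(sum(pm[, 1L] * w), sum(pm[, 2L] * w)) * h1 * h2,
                   tallies = tal, n_params = 2L),
              class = "crm_posterior")
  }
}

.posterior_grid_2d <- 401L

# E[h(params)] under the posterior.
posterior_expect <- function(fit, h) {
  if (fit$n_params == 1L) trapz(fit$grid, h(fit$grid) * fit$w)
  else sum(h(fit$grid) * fit$w) * fit$cell
}

# Per-dose probabilities F(params, d_i) on the quadrature grid (matrix:
# grid points x doses).
posterior_prob_matrix <- function(fit) {
  pm <- if (fit$n_params == 1L) matrix(fit$grid, ncol = 1L) else fit$grid
  vapply(fit$labels,
         function(d) exp(.log_prob_dlt(fit$model, pm, d)[, 1L]),
         numeric(nrow(pm)))
}

# Quantile of the induced distribution of F(params, d) for one dose.
posterior_prob_quantile <- function(fit, probs_at_dose, q) {
  o <- order(probs_at_dose)
  x <- probs_at_dose[o]
  wts <- if (fit$n_params == 1L) {
    h <- fit$grid[2L] - fit$grid[1L]  # uniform grid
    w <- fit$w * h
    w[c(1L, length(w))] <- w[c(1L, length(w))] / 2
    w[o]
  } else fit$w[o] * fit$cell
  cw <- cumsum(wts) / sum(wts)
  vapply(q, function(qq) x[which.max(cw >= qq)], numeric(1))
}

#' Bayesian per-dose DLT-probability estimates
#'
#' Updates the prior on the model parameter(s) with the accrued binary DLT
#' data by deterministic quadrature, and reports a central DLT-probability
#' estimate plus equal-tailed credible bounds for every dose.
#'
#' Two central-estimate conventions are supported, and both occur in
#' practice: `"plugin_at_posterior_mean"` plugs the posterior mean of the
#' parameter(s) into the dose-toxicity function, while
#' `"posterior_mean_of_prob"` averages the induced per-dose DLT probability
#' over the posterior. Interval bounds are always percentiles of the induced
#' per-dose probability distribution (2.5th/97.5th at the default level).
#'
#' @param model A [crm_model()].
#' @param labels Dose labels from [dose_labels()].
#' @param prior A [crm_prior()] (list of two for `logistic2`).
#' @param data Patient records ([patient_records()]); may be empty.
#' @param interval_level Credible level for the bounds (default 0.95).
#' @param convention `"plugin_at_posterior_mean"` or
#'   `"posterior_mean_of_prob"`.
#' @return A `tox_estimates` data frame with columns `dose`, `label`, `n`,
#'   `dlt`, `estimate`, `lower`, `upper`, and attributes `convention`,
#'   `level` and `param_summary`.
#' @examples
#' m <- crm_model("logistic1", slope_link = "identity")
#' pr <- crm_prior("exponential", rate = 1, central = "median")
#' lab <- dose_labels(m, c(0.05, 0.1, 0.15, 0.33, 0.5), prior_central(pr))
#' posterior_estimates(m, lab, pr, patient_records(c(1, 1, 1), c(0, 0, 0)))
#' @export
posterior_estimates <- function(model, labels, prior, data,
                                interval_level = 0.95,
                                convention = c("plugin_at_posterior_mean",
                                               "posterior_mean_of_prob")) {
  convention <- match.arg(convention)
  fit <- posterior_fit(model, labels, prior, data)
  probs <- posterior_prob_matrix(fit)
  central <- if (convention == "plugin_at_posterior_mean") {
    prob_dlt_many(model, fit$post_mean, labels)
  } else {
    if (fit$n_params == 1L)
      vapply(seq_along(labels), function(i) trapz(fit$grid, probs[, i] * fit$w),
             numeric(1))
    else colSums(probs * fit$w) * fit$cell
  }
  a <- (1 - interval_level) / 2
  bounds <- vapply(seq_along(labels), function(i)
    posterior_prob_quantile(fit, probs[, i], c(a, 1 - a)), numeric(2))
  out <- data.frame(dose = seq_along(labels), label = labels,
                    n = fit$tallies$n, dlt = fit$tallies$y,
                    estimate = central, lower = bounds[1L, ],
                    upper = bounds[2L, ])
  structure(out, class = c("tox_estimates", "data.frame"),
            convention = convention, level = interval_level,
            param_summary = list(post_mean = fit$post_mean,
                                 post_median = fit$post_median))
}

#' @export
print.tox_estimates <- function(x, ...) {
  cat(sprintf("Per-dose DLT-probability estimates (%s, %.0f%% interval)\n",
              attr(x, "convention"), 100 * attr(x, "level")))
  print.data.frame(cbind(x[, c("dose", "n", "dlt")],
                         round(x[, c("estimate", "lower", "upper")], 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Posterior tail probability of excessive toxicity at a dose
#'
#' \eqn{P(p_{dose} > threshold \mid data)} by quadrature; this is the
#' quantity behind safety stopping rules of the form "stop if the chance
#' that the risk of DLT at the lowest dose exceeds the TTL by some margin is
#' high".
#'
#' @inheritParams posterior_estimates
#' @param dose_index Which dose to evaluate.
#' @param threshold Probability threshold.
#' @return A single probability.
#' @export
posterior_tail <- function(model, labels, prior, data, dose_index, threshold) {
  stopifnot(dose_index >= 1L, dose_index <= length(labels))
  if (threshold <= 0) return(1)
  if (threshold >= 1) return(0)
  fit <- posterior_fit(model, labels, prior, data)
  pm <- if (fit$n_params == 1L) matrix(fit$grid, ncol = 1L) else fit$grid
  p <- exp(.log_prob_dlt(fit$model, pm, labels[dose_index])[, 1L])
  posterior_expect(fit, function(g) as.numeric(p > threshold))
}

# ---- maximum likelihood ---------------------------------------------------

loglik_fun <- function(model, labels, tal) {
  idx <- which(tal$n > 0L)
  function(params) {
    pm <- matrix(params, nrow = 1L)
    ll <- 0
    for (i in idx) {
      l2 <- .log_prob_dlt(model, pm, labels[i])
      ll <- ll + tal$y[i] * l2[1L, 1L] + (tal$n[i] - tal$y[i]) * l2[1L, 2L]
    }
    ll
  }
}

.mle_bounds <- function(model) {
  if (model$slope_link == "exp") c(-15, 15) else c(1e-8, 100)
}

#' Maximum-likelihood per-dose DLT-probability estimates
#'
#' Fits the model parameter(s) by bounded numerical optimisation of the
#' binomial likelihood and reports plug-in estimates at the MLE. The data
#' must be heterogeneous — at least one DLT and one non-DLT — otherwise the
#' likelihood has no interior maximum and the caller should remain in the
#' rule-based first stage of a two-stage design.
#'
#' Confidence bounds come from profile-likelihood inversion of the
#' likelihood-ratio statistic on the parameter, mapped through the monotone
#' dose-toxicity function (one-parameter families); for `logistic2` a
#' Wald interval on the logit scale is used and flagged in the
#' `ci_method` attribute.
#'
#' @inheritParams posterior_estimates
#' @return A `tox_estimates` data frame (see [posterior_estimates()]) with
#'   attributes `convention = "mle"`, `param_summary` and `ci_method`.
#' @export
mle_estimates <- function(model, labels, data, interval_level = 0.95) {
  k <- length(labels)
  tal <- dose_tallies(data, k)
  if (sum(tal$y) == 0L || sum(tal$y) == sum(tal$n))
    stop(paste("heterogeneity required: maximum likelihood needs at least",
               "one DLT and one non-DLT response"), call. = FALSE)
  ll <- loglik_fun(model, labels, tal)
  if (model$n_params == 1L) {
    b <- .mle_bounds(model)
    opt <- stats::optimize(ll, interval = b, maximum = TRUE, tol = 1e-9)
    mle <- opt$maximum
    llmax <- opt$objective
    crit <- stats::qchisq(interval_level, df = 1) / 2
    f <- function(x) llmax - ll(x) - crit
    lo <- if (f(b[1L]) > 0)
      stats::uniroot(f, c(b[1L], mle), tol = 1e-9)$root else b[1L]
    hi <- if (f(b[2L]) > 0)
      stats::uniroot(f, c(mle, b[2L]), tol = 1e-9)$root else b[2L]
    est <- prob_dlt_many(model, mle, labels)
    p_lo <- prob_dlt_many(model, lo, labels)
    p_hi <- prob_dlt_many(model, hi, labels)
    out <- data.frame(dose = seq_len(k), label = labels, n = tal$n,
                      dlt = tal$y, estimate = est,
                      lower = pmin(p_lo, p_hi), upper = pmax(p_lo, p_hi))
    structure(out, class = c("tox_estimates", "data.frame"),
              convention = "mle", level = interval_level,
              param_summary = list(mle = mle, ci = c(lo, hi)),
              ci_method = "profile_likelihood")
  } else {
    start <- c(0, if (model$slope_link == "exp") 0 else 1)
    opt <- stats::optim(start, function(p) -ll(p), hessian = TRUE,
                        method = "BFGS")
    mle <- opt$par
    est <- prob_dlt_many(model, mle, labels)
    # Wald interval on the linear predictor via the delta method.
    vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    zq <- stats::qnorm(1 - (1 - interval_level) / 2)
    if (is.null(vc)) {
      lo <- rep(0, k); hi <- rep(1, k)
    } else {
      s2 <- .slope(model, mle[2L])
      bnds <- vapply(labels, function(d) {
        grad <- c(1, if (model$slope_link == "exp") s2 * d else d)
        se <- sqrt(max(0, drop(t(grad) %*% vc %*% grad)))
        eta <- mle[1L] + s2 * d
        stats::plogis(eta + c(-1, 1) * zq * se)
      }, numeric(2))
      lo <- bnds[1L, ]; hi <- bnds[2L, ]
    }
    out <- data.frame(dose = seq_len(k), label = labels, n = tal$n,
                      dlt = tal$y, estimate = est, lower = lo, upper = hi)
    structure(out, class = c("tox_estimates", "data.frame"),
              convention = "mle", level = interval_level,
              param_summary = list(mle = mle),
              ci_method = "wald_logit")
  }
}
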