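#' Dose panel
#'
#' The set of actual drug doses under investigation, in increasing order,
#' together with the unit they are expressed in. The panel fixes `k`, the
#' number of dose levels of the trial.
#'
#' @param doses Numeric vector of actual doses, strictly increasing, all
#'   positive.
#' @param unit Free-text unit label, e.g. `"mg/m^2/day"` or `"ng/kg"`.
#' @return An object of class `dose_panel` with elements `doses`, `unit`
#'   and `k`.
#' @examples
#' dose_panel(c(0.5, 1, 3, 5, 6), "mg/m^2/day")
#' @export
dose_panel <- function(doses, unit) {
  doses <- as.numeric(doses)
  if (length(doses) < 2L)
    stop("a dose panel needs at least two dose levels", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("actual doses must be finite and positive", call. = FALSE)
  if (any(diff(doses) <= 0))
    stop("actual doses must be strictly increasing", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("'unit' must be a non-empty string", call. = FALSE)
  structure(list(doses = doses, unit = unit, k = length(doses)),
            class = "dose_panel")
}

#' @export
print.dose_panel <- function(x, ...) {
  cat("Dose panel:", paste(x$doses, collapse = ", "), x$unit,
      sprintf("(%d levels)\n", x$k))
  invisible(x)
}

#' Dose-toxicity model specification
#'
#' The CRM works on a fixed parametric dose-toxicity function
#' \eqn{F(\beta, d)} that is strictly increasing in the working-scale dose
#' label \eqn{d}. Three standard families are supported:
#'
#' * `power` (empiric): \eqn{F(\beta, d) = d^{\exp(\beta)}}, labels in (0,1);
#' * `logistic1`: \eqn{F(\beta, d) = \mathrm{logit}^{-1}(c + \exp(\beta) d)}
#'   with fixed intercept \eqn{c} (default 3);
#' * `logistic2`: \eqn{F(\beta, d) = \mathrm{logit}^{-1}(\beta_1 +
#'   \exp(\beta_2) d)} with both intercept and slope free.
#'
#' The slope can either enter as \eqn{\exp(\beta)} with \eqn{\beta}
#' unconstrained (`slope_link = "exp"`, the textbook parameterisation), or
#' as a raw positive parameter \eqn{a > 0} (`slope_link = "identity"`),
#' which is the natural pairing with positive-support priors such as the
#' exponential prior used in the ssHHT leukaemia trial.
#'
#' @param family One of `"power"`, `"logistic1"`, `"logistic2"`.
#' @param intercept Fixed intercept for `logistic1` (default 3). Ignored by
#'   the other families.
#' @param slope_link `"exp"` or `"identity"`.
#' @return An object of class `crm_model`.
#' @examples
#' crm_model("logistic1", intercept = 3, slope_link = "identity")
#' @export
crm_model <- function(family = c("power", "logistic1", "logistic2"),
                      intercept = 3, slope_link = c("exp", "identity")) {
  family <- match.arg(family)
  slope_link <- match.arg(slope_link)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("'intercept' must be a single finite number", call. = FALSE)
  structure(list(family = family, intercept = intercept,
                 slope_link = slope_link,
                 n_params = if (family == "logistic2") 2L else 1L),
            class = "crm_model")
}

#' @export
print.crm_model <- function(x, ...) {
  cat(sprintf("CRM dose-toxicity model: %s (slope link: %s%s)\n", x$family,
              x$slope_link,
              if (x$family == "logistic1")
                sprintf(", intercept %g", x$intercept) else ""))
  invisible(x)
}

# Effective slope given the raw slope parameter under the configured link.
.slope <- function(model, raw) {
  if (model$slope_link == "exp") exp(raw) else raw
}

#' Probability of dose-limiting toxicity under a model
#'
#' Evaluates \eqn{F(\beta, d)} for the chosen model family at one or more
#' dose labels.
#'
#' @param model A [crm_model()].
#' @param params Parameter vector: length 1 for `power`/`logistic1`
#'   (the slope parameter), length 2 (`intercept`, `slope`) for `logistic2`.
#' @param label Numeric vector of dose labels on the model's working scale.
#'   The `power` family requires labels in the open interval (0, 1).
#' @return Vector of DLT probabilities, same length as `label`.
#' @examples
#' m <- crm_model("logistic1", slope_link = "identity")
#' prob_dlt(m, 1, -3) # logit argument zero -> 0.5
#' @export
prob_dlt <- function(model, params, label) {
  stopifnot(inherits(model, "crm_model"))
  if (length(params) != model$n_params)
    stop(sprintf("model family '%s' takes %d parameter(s), got %d",
                 model$family, model$n_params, length(params)), call. = FALSE)
  switch(model$family,
    power = {
      if (any(label <= 0 | label >= 1))
        stop("power-family dose labels must lie in (0, 1)", call. = FALSE)
      exp(.slope(model, params[1L]) * log(label))
    },
    logistic1 = stats::plogis(model$intercept + .slope(model, params[1L]) * label),
    logistic2 = stats::plogis(params[1L] + .slope(model, params[2L]) * label)
  )
}

# log F and log(1 - F), vectorised over a grid of slope values for a single
# label; used by the likelihood. `params` is a matrix with one row per grid
# point (1 or 2 columns).
.log_prob_dlt <- function(model, params, label) {
  switch(model$family,
    power = {
      s <- .slope(model, params[, 1L])
      lp <- s * log(label)
      cbind(lp, log1p(-exp(lp)))
    },
    logistic1 = {
      eta <- model$intercept + .slope(model, params[, 1L]) * label
      cbind(stats::plogis(eta, log.p = TRUE), stats::plogis(-eta, log.p = TRUE))
    },
    logistic2 = {
      eta <- params[, 1L] + .slope(model, params[, 2L]) * label
      cbind(stats::plogis(eta, log.p = TRUE), stats::plogis(-eta, log.p = TRUE))
    }
  )
}

#' Dose labels from a skeleton
#'
#' Inverts the dose-toxicity function at the central parameter value
#' \eqn{\beta^*} (prior mean or median) so that
#' \eqn{F(\beta^*, d_i) = p_i} holds exactly for every skeleton probability
#' \eqn{p_i}. The actual dose scale of the drug plays no role: the labels
#' guarantee the model passes through the clinicians' prior DLT-risk guesses
#' before any data accrue.
#'
#' @param model A [crm_model()].
#' @param skeleton Strictly increasing vector of prior DLT probabilities in
#'   (0, 1).
#' @param central_param Central parameter value(s) \eqn{\beta^*}: length 1
#'   for one-parameter families, length 2 for `logistic2`.
#' @return Numeric vector of dose labels, strictly increasing.
#' @examples
#' m <- crm_model("power")
#' dose_labels(m, c(0.05, 0.1, 0.15, 0.33, 0.5), 0) # equals the skeleton
#' @export
dose_labels <- function(model, skeleton, central_param) {
  stopifnot(inherits(model, "crm_model"))
  assert_skeleton(skeleton)
  if (length(central_param) != model$n_params)
    stop("central_param length does not match the model family", call. = FALSE)
  lab <- switch(model$family,
    power = exp(log(skeleton) / .slope(model, central_param[1L])),
    logistic1 = (stats::qlogis(skeleton) - model$intercept) /
      .slope(model, central_param[1L]),
    logistic2 = (stats::qlogis(skeleton) - central_param[1L]) /
      .slope(model, central_param[2L])
  )
  if (any(diff(lab) <= 0))
    stop("dose labels are not strictly increasing; check the skeleton",
         call. = FALSE)
  lab
}

# Hard validation used internally; the user-facing report lives in
# validate_skeleton().
assert_skeleton <- function(skeleton) {
  if (!is.numeric(skeleton) || length(skeleton) < 2L)
    stop("skeleton must be a numeric vector of length >= 2", call. = FALSE)
  if (any(skeleton <= 0 | skeleton >= 1))
    stop("skeleton probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  if (any(diff(skeleton) <= 0))
    stop("skeleton probabilities must be strictly increasing", call. = FALSE)
  invisible(skeleton)
}

#' Validate a dose-toxicity skeleton
#'
#' Checks a skeleton for monotonicity and boundary problems and reports its
#' spacing and the prior MTD (the dose whose skeleton probability is closest
#' to the TTL). Spacing flags are advisory: prior DLT probabilities packed
#' too closely slow escalation down, while probabilities spread too far
#' apart hurt convergence towards the MTD.
#'
#' @param skeleton Numeric vector of prior DLT probabilities.
#' @param ttl Target toxicity level in (0, 1).
#' @return An object of class `skeleton_report`: a list with `valid`,
#'   `problems` (character vector of hard failures), `warnings` (advisory
#'   flags), `prior_mtd` (index, or `NA` if invalid), `min_gap`, `max_gap`.
#' @examples
#' validate_skeleton(c(0.05, 0.10, 0.15, 0.33, 0.50), ttl = 0.33)
#' @export
validate_skeleton <- function(skeleton, ttl) {
  stopifnot(is.numeric(ttl), length(ttl) == 1L, ttl > 0, ttl < 1)
  problems <- character()
  warnings <- character()
  if (!is.numeric(skeleton) || length(skeleton) < 2L)
    problems <- c(problems, "skeleton must be numeric of length >= 2")
  if (any(skeleton <= 0 | skeleton >= 1))
    problems <- c(problems, "probabilities on or outside the (0, 1) boundary")
  if (any(diff(skeleton) <= 0))
    problems <- c(problems, "not strictly increasing")
  valid <- length(problems) == 0L
  min_gap <- max_gap <- prior_mtd <- NA_real_
  if (valid) {
    gaps <- diff(skeleton)
    min_gap <- min(gaps)
    max_gap <- max(gaps)
    prior_mtd <- which.min(abs(skeleton - ttl))
    if (min_gap < 0.02)
      warnings <- c(warnings, sprintf(
        "adjacent skeleton probabilities only %.3f apart: escalation may be slow",
        min_gap))
    if (max_gap > 0.30)
      warnings <- c(warnings, sprintf(
        "adjacent skeleton gap of %.3f: convergence to the MTD may be poor",
        max_gap))
    if (min(abs(skeleton - ttl)) >= 0.15)
      warnings <- c(warnings,
                    "no skeleton probability within 0.15 of the TTL")
  }
  structure(list(valid = valid, problems = problems, warnings = warnings,
                 prior_mtd = if (valid) as.integer(prior_mtd) else NA_integer_,
                 min_gap = min_gap, max_gap = max_gap,
                 skeleton = skeleton, ttl = ttl),
            class = "skeleton_report")
}

#' @export
print.skeleton_report <- function(x, ...) {
  cat("Skeleton:", paste(format(x$skeleton), collapse = ", "),
      sprintf("(TTL %.2f)\n", x$ttl))
  if (x$valid) {
    cat(sprintf("  valid; prior MTD at dose %d; adjacent gaps in [%.3f, %.3f]\n",
                x$prior_mtd, x$min_gap, x$max_gap))
  } else {
    cat("  INVALID:", paste(x$problems, collapse = "; "), "\n")
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

# Solve the slope parameter s such that F(s, label) = p, for the
# one-parameter families (raw effective slope, regardless of link).
.solve_slope <- function(model, label, p) {
  switch(model$family,
    power = log(p) / log(label),
    logistic1 = (stats::qlogis(p) - model$intercept) / label,
    stop("indifference-interval calibration needs a one-parameter model",
         call. = FALSE)
  )
}

# Invert F at a fixed effective slope s: the label where F(s, d) = p.
.solve_label <- function(model, s, p) {
  switch(model$family,
    power = exp(log(p) / s),
    logistic1 = (stats::qlogis(p) - model$intercept) / s
  )
}

#' Calibrate a skeleton from a TTL and an indifference interval
#'
#' Builds a skeleton by the indifference-interval recursion of Lee and
#' Cheung. The clinician states the TTL \eqn{\theta}, a half-width
#' \eqn{\delta} (the MTD's true DLT probability is acceptable anywhere in
#' \eqn{[\theta - \delta, \theta + \delta]}), and the prior guess of the MTD
#' position. The skeleton probability at the prior MTD is set to
#' \eqn{\theta}; adjacent probabilities are then solved outwards so that at
#' the parameter value where one dose sits on the edge of the indifference
#' interval, its neighbour sits on the opposite edge — the model is then
#' indifferent between the two, and consecutive doses' indifference
#' intervals tile the probability scale.
#'
#' Concretely, going up from level \eqn{i}: find the effective slope
#' \eqn{s} with \eqn{F(s, d_i) = \theta - \delta}, set
#' \eqn{d_{i+1}} from \eqn{F(s, d_{i+1}) = \theta + \delta}, and take
#' \eqn{p_{i+1} = F(s^*, d_{i+1})} at the reference slope \eqn{s^* = 1}
#' (i.e. \eqn{\beta^* = 0} under the exponential slope link). Going down is
#' symmetric with the interval edges swapped.
#'
#' @param ttl Target toxicity level \eqn{\theta} in (0, 1).
#' @param halfwidth Indifference half-width \eqn{\delta}, with
#'   `0 < halfwidth < min(ttl, 1 - ttl)`.
#' @param prior_mtd_index Position (1..k) of the prior MTD guess.
#' @param k Number of dose levels.
#' @param model A one-parameter [crm_model()] (`power` or `logistic1`).
#' @return Numeric skeleton of length `k` with attribute
#'   `indifference_interval = c(ttl - halfwidth, ttl + halfwidth)`.
#' @examples
#' skeleton_from_indifference(0.25, 0.05, prior_mtd_index = 3, k = 5,
#'                            model = crm_model("power"))
#' @export
skeleton_from_indifference <- function(ttl, halfwidth, prior_mtd_index, k,
                                       model = crm_model("power")) {
  stopifnot(inherits(model, "crm_model"))
  if (model$n_params != 1L)
    stop("indifference-interval calibration is defined for one-parameter models",
         call. = FALSE)
  stopifnot(is.numeric(ttl), length(ttl) == 1L, ttl > 0, ttl < 1)
  if (!(halfwidth > 0 && halfwidth < min(ttl, 1 - ttl)))
    stop("'halfwidth' must satisfy 0 < halfwidth < min(ttl, 1 - ttl)",
         call. = FALSE)
  k <- as.integer(k)
  prior_mtd_index <- as.integer(prior_mtd_index)
  stopifnot(k >= 2L, prior_mtd_index >= 1L, prior_mtd_index <= k)

  lab <- rep(NA_real_, k)
  lab[prior_mtd_index] <- .solve_label(model, 1, ttl)
  if (prior_mtd_index < k) {
    for (i in prior_mtd_index:(k - 1L)) {
      s <- .solve_slope(model, lab[i], ttl - halfwidth)
      lab[i + 1L] <- .solve_label(model, s, ttl + halfwidth)
    }
  }
  if (prior_mtd_index > 1L) {
    for (i in prior_mtd_index:2L) {
      s <- .solve_slope(model, lab[i], ttl + halfwidth)
      lab[i - 1L] <- .solve_label(model, s, ttl - halfwidth)
    }
  }
  ref_param <- if (model$slope_link == "exp") 0 else 1  # effective slope 1
  skel <- prob_dlt_many(model, ref_param, lab)
  bad <- which(skel <= 0 | skel >= 1 | !is.finite(skel))
  if (length(bad))
    stop(sprintf("indifference recursion left (0, 1) at dose level %d; %s",
                 bad[1L],
                 "reduce k, the halfwidth, or move the prior MTD guess"),
         call. = FALSE)
  if (any(diff(skel) <= 0))
    stop("indifference recursion produced a non-increasing skeleton",
         call. = FALSE)
  structure(skel,
            indifference_interval = c(ttl - halfwidth, ttl + halfwidth))
}

# prob_dlt without the power-domain error, for internal use where labels are
# known valid by construction.
prob_dlt_many <- function(model, params, labels) {
  vapply(labels, function(d) prob_dlt(model, params, d), numeric(1))
}
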