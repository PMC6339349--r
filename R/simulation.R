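#' Dose-toxicity scenario
#'
#' @param name Scenario label.
#' @param true_probs True DLT probability per dose; stress scenarios need
#'   not be monotone.
#' @param ttl TTL used to label the true MTD (dose with true probability
#'   closest to the TTL); pass `true_mtd = NA` for scenarios where no dose
#'   is acceptable.
#' @param true_mtd Optional explicit true MTD index.
#' @return An object of class `crm_scenario`.
#' @export
crm_scenario <- function(name, true_probs, ttl = NULL, true_mtd = NULL) {
  stopifnot(is.numeric(true_probs), all(true_probs >= 0 & true_probs <= 1))
  if (is.null(true_mtd)) {
    true_mtd <- if (is.null(ttl)) NA_integer_ else
      which.min(abs(true_probs - ttl))
  }
  structure(list(name = as.character(name), true_probs = true_probs,
                 true_mtd = as.integer(true_mtd)),
            class = "crm_scenario")
}

#' Standard scenario suite for pre-trial simulations
#'
#' Builds the recommended set of dose-toxicity scenarios: one scenario per
#' dose level in which that dose is exactly the MTD (its true DLT
#' probability equals the TTL), plus the two extremes — every dose above the
#' MTD (the lowest dose is already too toxic) and every dose below it.
#' Curves are generated by power-transforming the skeleton,
#' \eqn{p_j^{\log(t)/\log(p_i)}}, which pins dose \eqn{i} at the target
#' while preserving monotonicity.
#'
#' @param skeleton Working skeleton used as the curve shape.
#' @param ttl Target toxicity level.
#' @param extreme_shift How far above/below the TTL the extreme scenarios
#'   put the boundary doses (default 0.15).
#' @return A list of [crm_scenario()] objects of length `k + 2`.
#' @export
scenario_suite <- function(skeleton, ttl, extreme_shift = 0.15) {
  assert_skeleton(skeleton)
  k <- length(skeleton)
  pin <- function(target, at) skeleton^(log(target) / log(skeleton[at]))
  sc <- lapply(seq_len(k), function(i)
    crm_scenario(sprintf("mtd_at_dose_%d", i), pin(ttl, i), ttl = ttl))
  lo <- min(ttl + extreme_shift, (1 + ttl) / 2)
  hi <- max(ttl - extreme_shift, ttl / 2)
  c(sc,
    list(crm_scenario("all_doses_too_toxic", pin(lo, 1L), true_mtd = NA),
         crm_scenario("all_doses_below_mtd", pin(hi, k), true_mtd = NA)))
}

# Draw one replication-indexed seed stream: common random numbers across
# designs come from giving replication r the same sub-seed everywhere.
replication_seeds <- function(seed, replications) {
  set.seed(seed)
  sample.int(.Machine$integer.max, replications)
}

#' Simulate a design's operating characteristics under one scenario
#'
#' Runs `replications` complete trials of the design, drawing each cohort's
#' DLT outcomes as independent Bernoulli draws at the assigned dose's true
#' probability, and tallies the operating characteristics: the MTD-selection
#' distribution, per-dose allocation, DLT counts, sample size and study
#' duration (cohorts times a fixed accrual interval). Identical seeds give
#' bitwise-identical results.
#'
#' @param design A [crm_design()], or [three_plus_three_design()] to route
#'   the rule-based comparator through the same interface.
#' @param scenario A [crm_scenario()].
#' @param replications Number of simulated trials.
#' @param seed RNG seed (required: recorded in the result for replication).
#' @param accrual_interval Time units per cohort for the duration summary.
#' @return An object of class `oc_result`.
#' @export
simulate_trials <- function(design, scenario, replications = 2000L,
                            seed, accrual_interval = 1) {
  stopifnot(inherits(scenario, "crm_scenario"), replications >= 1L)
  R <- as.integer(replications)
  k <- length(scenario$true_probs)
  if (inherits(design, "three_plus_three_design")) {
    stopifnot(design$k == k)
    sim <- three_plus_three_simulate(scenario$true_probs, R, seed = seed)
    mtd_idx <- sim$mtd
    nvec <- sim$n
    dltvec <- sim$dlts
    alloc <- sim$alloc
    dlt_by_dose <- sim$dlt_by_dose
    duration <- nvec / 3 * accrual_interval
    per_dose_known <- TRUE
  } else {
    stopifnot(inherits(design, "crm_design"), design$panel$k == k)
    seeds <- replication_seeds(seed, R)
    mtd_idx <- integer(R)
    nvec <- integer(R)
    dltvec <- integer(R)
    alloc <- matrix(0L, R, k)
    dlt_by_dose <- matrix(0L, R, k)
    duration <- numeric(R)
    for (r in seq_len(R)) {
      set.seed(seeds[r])
      oracle <- function(patient, dose)
        list(dlt = stats::rbinom(1L, 1L, scenario$true_probs[dose]),
             moderate = 0L)
      res <- run_crm_trial(design, oracle)
      tal <- dose_tallies(res$state$records, k)
      mtd_idx[r] <- if (is.na(res$mtd)) 0L else res$mtd
      nvec[r] <- nrow(res$state$records)
      dltvec[r] <- sum(tal$y)
      alloc[r, ] <- tal$n
      dlt_by_dose[r, ] <- tal$y
      duration[r] <- res$n_cohorts * accrual_interval
    }
    per_dose_known <- TRUE
  }
  sel <- tabulate(mtd_idx + 1L, k + 1L) / R
  names(sel) <- c("none", paste0("dose", seq_len(k)))
  mean_alloc <- colMeans(alloc)
  prop_alloc <- if (sum(mean_alloc) > 0) mean_alloc / sum(mean_alloc) else
    mean_alloc
  structure(list(
    design_label = if (inherits(design, "three_plus_three_design"))
      "3+3" else "CRM",
    scenario = scenario,
    selection = sel,
    correct_selection = if (is.na(scenario$true_mtd)) NA_real_ else
      unname(sel[scenario$true_mtd + 1L]),
    allocation_mean = mean_alloc,
    allocation_prop = prop_alloc,
    dlt_by_dose_mean = colMeans(dlt_by_dose),
    per_dose_known = per_dose_known,
    mean_dlt = mean(dltvec),
    sample_size = list(mean = mean(nvec),
                       quantiles = stats::quantile(nvec,
                                                   c(0.025, 0.25, 0.5, 0.75,
                                                     0.975))),
    mean_duration = mean(duration),
    replications = R, seed = seed),
    class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s on '%s' (%d replications, seed %s)\n",
              x$design_label, x$scenario$name, x$replications,
              format(x$seed)))
  cat("  MTD selection:\n")
  print(round(x$selection, 3))
  cat(sprintf("  mean n %.1f, mean DLTs %.2f, mean duration %.1f\n",
              x$sample_size$mean, x$mean_dlt, x$mean_duration))
  invisible(x)
}

#' 3+3 comparator marker
#'
#' A stand-in design object routing the 3+3 rule-based design through
#' [simulate_trials()] and [compare_designs()].
#'
#' @param k Number of dose levels.
#' @return An object of class `three_plus_three_design`.
#' @export
three_plus_three_design <- function(k) {
  structure(list(k = as.integer(k)), class = "three_plus_three_design")
}

#' Compare competing designs across scenarios
#'
#' Runs every design on every scenario with common random numbers (the same
#' replication-indexed seed streams for all designs) and returns one row per
#' design x scenario cell.
#'
#' @param designs Named list of designs ([crm_design()] or
#'   [three_plus_three_design()]).
#' @param scenarios List of [crm_scenario()] objects.
#' @param replications Replications per cell.
#' @param seed Master seed.
#' @return An object of class `design_comparison`: a data frame with
#'   selection probabilities, correct-selection probability, mean sample
#'   size, mean DLTs and mean allocation at the true MTD, plus the full
#'   `oc_result` objects in the `results` attribute.
#' @export
compare_designs <- function(designs, scenarios, replications = 2000L, seed) {
  stopifnot(length(designs) >= 2L || is.null(names(designs)) == FALSE,
            length(scenarios) >= 1L)
  if (is.null(names(designs)))
    names(designs) <- paste0("design", seq_along(designs))
  rows <- list()
  results <- list()
  for (di in seq_along(designs)) {
    for (si in seq_along(scenarios)) {
      oc <- simulate_trials(designs[[di]], scenarios[[si]],
                            replications = replications, seed = seed)
      sc <- scenarios[[si]]
      alloc_mtd <- if (is.na(sc$true_mtd) || !oc$per_dose_known) NA_real_ else
        oc$allocation_mean[sc$true_mtd]
      rows[[length(rows) + 1L]] <- data.frame(
        design = names(designs)[di], scenario = sc$name,
        correct_selection = oc$correct_selection,
        mean_n = oc$sample_size$mean, mean_dlt = oc$mean_dlt,
        mean_patients_at_true_mtd = alloc_mtd,
        t(oc$selection))
      results[[paste(names(designs)[di], sc$name, sep = ".")]] <- oc
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("design_comparison", "data.frame"),
            results = results, seed = seed, replications = replications)
}
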