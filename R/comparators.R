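#' 3+3 design state
#'
#' @param k Number of dose levels.
#' @return An object of class `three_plus_three_state`.
#' @export
three_plus_three_state <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(k = k, dose = 1L, n = integer(k), dlt = integer(k),
                 phase = "first_triplet", mtd = NA_integer_,
                 finished = FALSE),
            class = "three_plus_three_state")
}

#' One step of the 3+3 design
#'
#' Applies the classical rules to one triplet's outcomes: with 0/3 DLTs
#' escalate (declaring the top dose the MTD if the panel is exhausted, the
#' complete-path convention); with 1/3 treat a second triplet at the same
#' dose; with 2 or more DLTs out of 3 or 6 stop and declare the dose below
#' the MTD (`mtd = 0` meaning "none" at the lowest dose); with at most 1/6
#' escalate.
#'
#' @param state A [three_plus_three_state()].
#' @param dlts_in_cohort DLT count in the current triplet (0..3).
#' @return The updated state. When `finished`, `mtd` holds the declared MTD
#'   dose index (0 = none).
#' @export
three_plus_three_step <- function(state, dlts_in_cohort) {
  stopifnot(inherits(state, "three_plus_three_state"))
  if (state$finished)
    stop("the 3+3 trial has already finished", call. = FALSE)
  d <- as.integer(dlts_in_cohort)
  stopifnot(d >= 0L, d <= 3L)
  i <- state$dose
  state$n[i] <- state$n[i] + 3L
  state$dlt[i] <- state$dlt[i] + d
  escalate <- function(s) {
    if (s$dose == s$k) {
      s$finished <- TRUE
      s$mtd <- s$k  # panel exhausted without excess toxicity
    } else {
      s$dose <- s$dose + 1L
      s$phase <- "first_triplet"
    }
    s
  }
  stop_below <- function(s) {
    s$finished <- TRUE
    s$mtd <- s$dose - 1L
    s
  }
  if (state$phase == "first_triplet") {
    if (d == 0L) state <- escalate(state)
    else if (d == 1L) state$phase <- "second_triplet"
    else state <- stop_below(state)
  } else {
    if (state$dlt[i] >= 2L) state <- stop_below(state)
    else state <- escalate(state)  # 1/6
  }
  state
}

#' Minimum patients dosed below a level under the 3+3
#'
#' A 3+3 design must treat at least three patients at every lower level
#' before it can reach dose `level`, so at least `3 * (level - 1)` patients
#' are dosed below it.
#'
#' @param level Dose index (1-based).
#' @return Patient count.
#' @examples
#' min_patients_below(4)  # 9
#' @export
min_patients_below <- function(level) {
  level <- as.integer(level)
  stopifnot(level >= 1L)
  3L * (level - 1L)
}

#' Exact operating characteristics of the 3+3 design
#'
#' Enumerates every reachable 3+3 path, weighting each triplet outcome by
#' its binomial probability under the true dose-toxicity curve, and returns
#' the exact distribution of the declared MTD, of the sample size, and of
#' the total DLT count.
#'
#' @param true_probs True DLT probabilities per dose.
#' @return An object of class `oc_exact`: list with `mtd_dist` (named
#'   vector: `none`, then one entry per dose), `sample_size_dist` (named by
#'   size), `dlt_dist` (named by count), `mean_n`, `mean_dlt`.
#' @export
three_plus_three_exact_oc <- function(true_probs) {
  stopifnot(is.numeric(true_probs), all(true_probs >= 0 & true_probs <= 1))
  k <- length(true_probs)
  mtd <- numeric(k + 1L)        # index 1 = none, 1 + j = dose j
  names(mtd) <- c("none", paste0("dose", seq_len(k)))
  nsz <- new.env(parent = emptyenv())
  dct <- new.env(parent = emptyenv())
  mean_n <- 0
  mean_dlt <- 0
  add <- function(env, key, p) {
    key <- as.character(key)
    assign(key, (if (exists(key, env)) get(key, env) else 0) + p, env)
  }
  walk <- function(state, prob, n, dlts) {
    if (state$finished) {
      mtd[state$mtd + 1L] <<- mtd[state$mtd + 1L] + prob
      add(nsz, n, prob)
      add(dct, dlts, prob)
      mean_n <<- mean_n + prob * n
      mean_dlt <<- mean_dlt + prob * dlts
      return(invisible())
    }
    p <- true_probs[state$dose]
    for (d in 0:3) {
      pd <- stats::dbinom(d, 3, p)
      if (pd == 0) next
      walk(three_plus_three_step(state, d), prob * pd, n + 3L, dlts + d)
    }
  }
  walk(three_plus_three_state(k), 1, 0L, 0L)
  as_dist <- function(env) {
    v <- unlist(as.list(env))
    v[order(as.numeric(names(v)))]
  }
  structure(list(mtd_dist = mtd, sample_size_dist = as_dist(nsz),
                 dlt_dist = as_dist(dct), mean_n = mean_n,
                 mean_dlt = mean_dlt, true_probs = true_probs),
            class = "oc_exact")
}

#' @export
print.oc_exact <- function(x, ...) {
  cat("Exact 3+3 operating characteristics\n")
  cat("  MTD distribution:\n")
  print(round(x$mtd_dist, 4))
  cat(sprintf("  mean sample size %.2f, mean DLTs %.2f\n", x$mean_n,
              x$mean_dlt))
  invisible(x)
}

# Vectorised Monte-Carlo simulation of 3+3 trials; used as the stochastic
# cross-check of the exact enumeration and by compare_designs().
three_plus_three_simulate <- function(true_probs, replications, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(true_probs)
  R <- as.integer(replications)
  dose <- rep(1L, R)
  phase2 <- rep(FALSE, R)
  first_dlts <- integer(R)
  n <- integer(R)
  dlts <- integer(R)
  mtd <- rep(NA_integer_, R)
  active <- rep(TRUE, R)
  alloc <- matrix(0L, R, k)
  dlt_by_dose <- matrix(0L, R, k)
  while (any(active)) {
    idx <- which(active)
    d <- stats::rbinom(length(idx), 3L, true_probs[dose[idx]])
    n[idx] <- n[idx] + 3L
    dlts[idx] <- dlts[idx] + d
    alloc[cbind(idx, dose[idx])] <- alloc[cbind(idx, dose[idx])] + 3L
    dlt_by_dose[cbind(idx, dose[idx])] <- dlt_by_dose[cbind(idx, dose[idx])] + d
    tot <- ifelse(phase2[idx], first_dlts[idx] + d, d)
    stop_tox <- tot >= 2L
    need_second <- !phase2[idx] & d == 1L
    escal <- !stop_tox & !need_second
    # stopping for toxicity
    s <- idx[stop_tox]
    mtd[s] <- dose[s] - 1L
    active[s] <- FALSE
    # second triplet
    s2 <- idx[need_second]
    phase2[s2] <- TRUE
    first_dlts[s2] <- 1L
    # escalation (or top-dose finish)
    e <- idx[escal]
    at_top <- dose[e] == k
    mtd[e[at_top]] <- k
    active[e[at_top]] <- FALSE
    up <- e[!at_top]
    dose[up] <- dose[up] + 1L
    phase2[up] <- FALSE
    first_dlts[up] <- 0L
  }
  sel <- tabulate(mtd + 1L, k + 1L) / R
  names(sel) <- c("none", paste0("dose", seq_len(k)))
  list(mtd_dist = sel, mean_n = mean(n), mean_dlt = mean(dlts),
       n = n, dlts = dlts, mtd = mtd, alloc = alloc,
       dlt_by_dose = dlt_by_dose)
}

#' Nonparametric benchmark design
#'
#' The complete-tolerance-profile benchmark: each simulated patient draws a
#' latent tolerance \eqn{u \sim U(0,1)} and their DLT status at *every* dose
#' is known (\eqn{u \le p_i}), as if the trial could observe each patient at
#' all doses. Each dose's toxicity rate is estimated from the complete
#' profiles and the dose closest to the TTL is selected. No implementable
#' design can use more information, so the benchmark's selection accuracy is
#' an upper reference for any design at the same sample size.
#'
#' @param true_probs True DLT probabilities per dose.
#' @param n Patients per simulated trial.
#' @param ttl Target toxicity level.
#' @param replications Number of simulated trials.
#' @param seed RNG seed (recorded in the result).
#' @return A list with `mtd_dist` (selection probabilities over doses),
#'   `replications`, `seed`.
#' @export
benchmark_oc <- function(true_probs, n, ttl, replications = 2000L,
                         seed = NULL) {
  stopifnot(n >= 1L, all(true_probs >= 0 & true_probs <= 1))
  if (!is.null(seed)) set.seed(seed)
  k <- length(true_probs)
  R <- as.integer(replications)
  sel <- integer(R)
  for (r in seq_len(R)) {
    u <- stats::runif(n)
    phat <- vapply(true_probs, function(p) mean(u <= p), numeric(1))
    sel[r] <- which.min(abs(phat - ttl))
  }
  dist <- tabulate(sel, k) / R
  names(dist) <- paste0("dose", seq_len(k))
  list(mtd_dist = dist, replications = R, seed = seed)
}
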