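#' Enumerate dose transition pathways
#'
#' Computes, ahead of time, every feasible sequence of dose assignments over
#' the next `depth_cohorts` cohorts implied by the possible DLT outcomes.
#' Outcomes branch by DLT count per cohort (0..cohort size): within-cohort
#' orderings are exchangeable for the binomial likelihood, so this
#' granularity is lossless. Every internal node's recommendation is
#' recomputed from its cumulative data through the full engine — inference,
#' decision rule, safety constraints and stopping rules.
#'
#' @param state A [trial_state()] (may be empty: the root then assigns the
#'   starting dose).
#' @param depth_cohorts How many future cohorts to enumerate.
#' @param max_nodes Guard against combinatorial blow-up (error above this).
#' @return The root `pathway_node`: a list with `dose` (assigned dose, `NA`
#'   if the node stops), `n_patients`, `stop`, `tallies` (cumulative
#'   per-dose patients/DLTs) and `children` (list indexed by DLT count + 1).
#' @seealso [pathway_table()] for a flat one-row-per-path rendering.
#' @export
enumerate_pathways <- function(state, depth_cohorts, max_nodes = 1e6) {
  stopifnot(inherits(state, "trial_state"), depth_cohorts >= 1L)
  c_size <- state$design$cohort_size
  # closed-form bound ignoring early stopping
  if ((c_size + 1)^depth_cohorts > max_nodes)
    stop(sprintf(paste0("pathway tree could exceed %g nodes; ",
                        "reduce depth_cohorts"), max_nodes), call. = FALSE)
  build <- function(st, depth) {
    rec <- next_cohort(st)
    tal <- dose_tallies(st$records, st$design$panel$k)
    node <- list(dose = rec$dose_index, n_patients = rec$n_patients,
                 stop = rec$stop, tallies = tal, children = NULL)
    if (is.null(rec$stop) && depth > 0L) {
      node$children <- lapply(0:rec$n_patients, function(j)
        build(record_cohort(st, rec$dose_index, j,
                            n_patients = rec$n_patients),
              depth - 1L))
      names(node$children) <- paste0("dlt", 0:rec$n_patients)
    }
    class(node) <- "pathway_node"
    node
  }
  build(state, depth_cohorts)
}

#' Flatten a pathway tree into the standard DTP table
#'
#' One row per root-to-leaf path; columns give each cohort's assigned dose
#' and hypothesised DLT count, and the final recommendation (the next dose
#' at the leaf, or the stop reason).
#'
#' @param root A `pathway_node` from [enumerate_pathways()].
#' @return A data frame.
#' @export
pathway_table <- function(root) {
  rows <- list()
  walk <- function(node, prefix) {
    if (is.null(node$children)) {
      rows[[length(rows) + 1L]] <<- c(prefix,
        next_dose = if (!is.null(node$stop)) NA_integer_ else node$dose,
        outcome = if (!is.null(node$stop))
          paste0("stop:", node$stop$rule) else "continue")
      return(invisible())
    }
    for (j in seq_along(node$children)) {
      step <- stats::setNames(
        list(node$dose, j - 1L),
        paste0(c("cohort", "dlts"), length(prefix) / 2 + 1L))
      walk(node$children[[j]], c(prefix, step))
    }
  }
  walk(root, list())
  cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    r[miss] <- NA
    as.data.frame(r[cols])
  }))
  rownames(df) <- NULL
  df
}

#' @export
print.pathway_node <- function(x, ..., indent = 0L) {
  pad <- strrep("  ", indent)
  if (!is.null(x$stop)) {
    cat(pad, "STOP (", x$stop$rule, ")\n", sep = "")
  } else {
    cat(pad, "dose ", x$dose, " x", x$n_patients, "\n", sep = "")
    if (!is.null(x$children))
      for (j in seq_along(x$children)) {
        cat(pad, " ", names(x$children)[j], " ->\n", sep = "")
        print(x$children[[j]], indent = indent + 1L)
      }
  }
  invisible(x)
}

#' Probability that the next m patients receive one dose
#'
#' Enumerates the pathways covering the next `m` patients and sums the
#' predictive probabilities of the branches in which every one of those
#' patients is assigned the same dose level. Branch outcome probabilities
#' come from the posterior predictive distribution (Bayesian designs) or the
#' plug-in binomial at the MLE (likelihood designs). With `scenario_free`,
#' the function short-circuits to exactly 1 when *every* branch assigns the
#' same dose regardless of outcomes — the reading used by the stopping rule
#' "the next m patients will receive the same dose whatever we observe".
#'
#' @param state A [trial_state()].
#' @param m Number of future patients.
#' @param scenario_free Short-circuit to exactly 1.0 when the same-dose
#'   property holds on every branch.
#' @return A probability.
#' @export
prob_next_m_same <- function(state, m, scenario_free = TRUE) {
  stopifnot(inherits(state, "trial_state"), m >= 1L)
  # The rule asks whether future dosing is stable; its own firing must not
  # influence the enumeration (it would recurse), so it is excluded from the
  # stopping rules applied along the hypothetical branches.
  state$design$stopping <- Filter(function(r) r$kind != "next_m_same_dose",
                                  state$design$stopping)
  rec0 <- next_cohort(state)
  if (!is.null(rec0$stop)) return(1)  # no further dosing: vacuously same
  target_dose <- rec0$dose_index
  all_same <- TRUE
  total <- 0
  walk <- function(st, remaining, prob) {
    rec <- next_cohort(st)
    if (!is.null(rec$stop)) {
      # trial stops before m further patients: no divergent dosing occurs
      total <<- total + prob
      return(invisible())
    }
    if (rec$dose_index != target_dose) {
      all_same <<- FALSE
      return(invisible())
    }
    if (remaining <= rec$n_patients) {
      total <<- total + prob
      return(invisible())
    }
    pj <- predictive_dlt_dist(st, rec$dose_index, rec$n_patients)
    for (j in 0:rec$n_patients) {
      walk(record_cohort(st, rec$dose_index, j, n_patients = rec$n_patients),
           remaining - rec$n_patients, prob * pj[j + 1L])
    }
  }
  walk(state, m, 1)
  if (scenario_free && all_same) 1 else total
}

#' Audit a design for coherent escalation
#'
#' Scans the full dose-transition-pathway tree to the given depth for any
#' edge where a cohort containing at least one DLT is immediately followed
#' by a strictly higher dose. Coherence is guaranteed for most CRM setups
#' but should be verified; an empty result means the design is coherent to
#' the audited depth.
#'
#' @param design A [crm_design()].
#' @param depth_cohorts Audit depth in cohorts.
#' @return A list of violations, each with the offending path (cohort-wise
#'   dose and DLT counts) and the escalation step; empty if coherent.
#' @export
coherence_audit <- function(design, depth_cohorts) {
  root <- enumerate_pathways(trial_state(design), depth_cohorts)
  violations <- list()
  walk <- function(node, path) {
    if (is.null(node$children)) return(invisible())
    for (j in seq_along(node$children)) {
      child <- node$children[[j]]
      dlts <- j - 1L
      if (dlts > 0L && !is.null(child$dose) && !is.na(child$dose) &&
          is.null(child$stop) && child$dose > node$dose) {
        violations[[length(violations) + 1L]] <<- list(
          path = path,
          step = sprintf("dose %d with %d DLT(s) followed by escalation to dose %d",
                         node$dose, dlts, child$dose))
      }
      walk(child, c(path, list(c(dose = node$dose, dlts = dlts))))
    }
  }
  walk(root, list())
  violations
}
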