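test_that("decision rules pick the dose matching the TTL", {
  est <- data.frame(estimate = c(0.10, 0.33, 0.60))
  expect_equal(recommend(est, 0.33, decision_rule("closest_to_ttl")), 2)
  expect_equal(recommend(est, 0.33, decision_rule("closest_not_exceeding")), 2)
  # ties go to the lower dose
  est2 <- data.frame(estimate = c(0.2, 0.4))
  expect_equal(recommend(est2, 0.3, decision_rule("closest_to_ttl")), 1)
  # conservative rule falls back to dose 1 when everything exceeds the TTL
  est3 <- data.frame(estimate = c(0.5, 0.6, 0.7))
  expect_equal(recommend(est3, 0.3, decision_rule("closest_not_exceeding")), 1)
  expect_equal(recommend(est3, 0.3, decision_rule("closest_to_ttl")), 1)
})

test_that("safety rules cap skipping and enforce coherence", {
  d <- tiny_design(k = 5, max_n = 30)
  st <- trial_state(d)
  st <- record_cohort(st, 1, 0)
  st <- record_cohort(st, 2, 0)
  expect_equal(apply_safety(5, st, safety_rules(no_skipping = TRUE)), 3)
  expect_equal(apply_safety(2, st, safety_rules(no_skipping = TRUE)), 2)

  st2 <- record_cohort(st, 3, 1)  # DLT in the most recent cohort
  expect_equal(
    apply_safety(4, st2, safety_rules(no_skipping = FALSE,
                                      enforce_coherence = TRUE)), 3)
  # first cohort is forced to the start dose
  st0 <- trial_state(d)
  expect_equal(apply_safety(4, st0, safety_rules(start_dose = 2)), 2)
})

test_that("stopping rules fire in configured order with max_n always enforced", {
  d <- tiny_design(k = 3, max_n = 9,
                   stopping = list(stop_consecutive_at_dose(6)))
  st <- trial_state(d)
  st <- record_cohort(st, 1, 0)
  expect_null(check_stopping(st))
  st <- record_cohort(st, 1, 0)
  hit <- check_stopping(st)  # 6 consecutive at dose 1
  expect_equal(hit$rule, "consecutive_at_dose")
  # max_n fires implicitly
  st2 <- trial_state(tiny_design(k = 3, max_n = 6))
  st2 <- record_cohort(st2, 1, 0)
  st2 <- record_cohort(st2, 2, 0)
  expect_equal(check_stopping(st2)$rule, "max_n")
})

test_that("the Viola-style excessive-toxicity rule stops a toxic trial", {
  d <- tiny_design(k = 3, max_n = 30,
                   stopping = list(stop_all_doses_toxic(margin = 0.10,
                                                        prob = 0.72)))
  st <- trial_state(d)
  st <- record_cohort(st, 1, 3)
  st <- record_cohort(st, 1, 3)
  hit <- check_stopping(st)
  expect_equal(hit$rule, "all_doses_toxic")
  # and a likelihood design cannot configure it
  expect_error(
    crm_design(panel = dose_panel(c(1, 2, 3), "mg"),
               skeleton = c(0.1, 0.2, 0.3), model = crm_model("power"),
               ttl = 0.25, max_n = 18, stage1 = stage1_config(),
               stopping = list(stop_all_doses_toxic())),
    "Bayesian")
})

test_that("next_cohort composes inference, decision and safety", {
  d <- tiny_design(k = 3, max_n = 9)
  st <- trial_state(d)
  rec <- next_cohort(st)
  expect_equal(rec$dose_index, 1)
  expect_equal(rec$reason, "first cohort")
  st <- record_cohort(st, 1, 0)
  rec2 <- next_cohort(st)
  expect_null(rec2$stop)
  expect_true(rec2$dose_index <= 2)  # no skipping past the next level
  expect_s3_class(rec2$estimates, "tox_estimates")
  # at max n the engine stops and recommends no dose
  st <- record_cohort(st, 2, 0)
  st <- record_cohort(st, 2, 0)
  rec3 <- next_cohort(st)
  expect_false(is.null(rec3$stop))
  expect_true(is.na(rec3$dose_index))
})

test_that("identical states yield identical recommendations", {
  d <- tiny_design(k = 4, max_n = 24)
  st <- trial_state(d)
  st <- record_cohort(st, 1, 0)
  st <- record_cohort(st, 2, 1)
  r1 <- next_cohort(st)
  r2 <- next_cohort(st)
  expect_identical(r1[c("dose_index", "unconstrained_dose_index")],
                   r2[c("dose_index", "unconstrained_dose_index")])
})

test_that("the ssHHT replay reproduces the published decision sequence", {
  d <- sshht_design_code()
  st <- trial_state(d)
  st <- record_cohort(st, 1, 0)              # 0/3 DLT at 0.5 mg/m^2/day
  rec1 <- next_cohort(st)
  expect_equal(rec1$unconstrained_dose_index, 5)   # model says top dose
  st <- record_cohort(st, 3, 1, note = "DSC override of dose-5 recommendation")
  rec2 <- next_cohort(st)
  expect_equal(rec2$dose_index, 4)           # 5 mg/m^2/day next
  for (i in 1:4) st <- record_cohort(st, 4, 1)
  expect_equal(nrow(st$records), 18)
  hit <- check_stopping(st)
  expect_false(is.null(hit))                 # trial stops at 18 patients
  est <- crmdose:::state_estimates(st)
  expect_equal(recommend(est, d$ttl, d$decision), 4)  # MTD = 5 mg/m^2/day
})

test_that("revising a DLT call changes later recommendations only through re-inference", {
  d <- tiny_design(k = 4, max_n = 24)
  recs <- patient_records(c(1, 1, 1, 2, 2, 2), c(0, 0, 0, 1, 0, 0),
                          cohort_id = rep(1:2, each = 3))
  st <- trial_state(d, recs)
  recs2 <- recs; recs2$dlt[4] <- 0L          # committee recodes the DLT
  st2 <- trial_state(d, recs2)
  fresh <- trial_state(d, recs2)
  expect_identical(next_cohort(st2)$dose_index, next_cohort(fresh)$dose_index)
  expect_identical(crmdose:::state_estimates(st2)$estimate,
                   crmdose:::state_estimates(fresh)$estimate)
  # and the revision does alter the inference
  expect_false(isTRUE(all.equal(crmdose:::state_estimates(st)$estimate,
                                crmdose:::state_estimates(st2)$estimate)))
})

two_stage_design <- function(max_n = 30) {
  crm_design(panel = dose_panel(2^(0:5), "ng/kg"),
             skeleton = c(0.02, 0.06, 0.12, 0.20, 0.30, 0.40),
             model = crm_model("power"), ttl = 0.20,
             cohort_size = 1, max_n = max_n,
             safety = safety_rules(no_skipping = TRUE, start_dose = 1),
             stage1 = stage1_config(cohort_size = 1))
}

test_that("stage 1 escalates singly and switches to the model at the first DLT", {
  d <- two_stage_design()
  oracle <- function(patient, dose)
    list(dlt = as.integer(patient == 4), moderate = 0L)
  res <- run_two_stage(d, oracle)
  recs <- res$state$records
  expect_equal(recs$dose_index[1:4], 1:4)     # one patient per level
  expect_equal(recs$dlt[4], 1L)
  expect_equal(crmdose:::trial_stage(res$state), "model_based")
  # all stage-1 data enter the likelihood: estimates exist and MTD declared
  expect_false(is.na(res$mtd))
  expect_s3_class(res$estimates, "tox_estimates")
})

test_that("a DLT-free stage 1 walks the panel once and stops at the top", {
  d <- two_stage_design()
  oracle <- function(patient, dose) list(dlt = 0L, moderate = 0L)
  res <- run_two_stage(d, oracle)
  expect_equal(res$state$records$dose_index, 1:6)
  expect_equal(res$stop$rule, "stage1_exhausted")
  expect_true(is.na(res$mtd))
})

test_that("moderate toxicity expands the dose to three patients before escalating", {
  d <- two_stage_design()
  oracle <- function(patient, dose)
    list(dlt = 0L, moderate = as.integer(patient == 2))
  res <- run_two_stage(d, oracle)
  recs <- res$state$records
  # patient 2 at dose 2 had moderate tox: patients 3 and 4 stay at dose 2,
  # then escalation continues
  expect_equal(recs$dose_index[2:5], c(2, 2, 2, 3))
})

test_that("a two-stage design may defer its skeleton until the stage switch", {
  d <- crm_design(panel = dose_panel(2^(0:3), "ng/kg"), skeleton = NULL,
                  model = crm_model("power"), ttl = 0.2, cohort_size = 1,
                  max_n = 12, stage1 = stage1_config())
  st <- trial_state(d)
  st <- record_cohort(st, 1, 0, n_patients = 1)
  expect_equal(next_cohort(st)$dose_index, 2)  # stage 1 needs no skeleton
  st <- record_cohort(st, 2, 1, n_patients = 1)
  expect_error(next_cohort(st), "skeleton")
  d2 <- set_skeleton(d, c(0.05, 0.1, 0.2, 0.35))
  st2 <- trial_state(d2, st$records)
  expect_false(is.null(next_cohort(st2)$dose_index))
})
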