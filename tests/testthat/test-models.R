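test_that("prob_dlt evaluates each family at hand-checkable points", {
  m1 <- crm_model("logistic1", intercept = 3, slope_link = "identity")
  expect_equal(prob_dlt(m1, 1, -3), 0.5)
  expect_equal(prob_dlt(m1, 1, log(0.33 / 0.67) - 3), 0.33)

  mp <- crm_model("power", slope_link = "exp")
  expect_equal(prob_dlt(mp, 0, 0.25), 0.25)  # exp(0) = 1: identity exponent

  m2 <- crm_model("logistic2", slope_link = "exp")
  expect_equal(prob_dlt(m2, c(0, 0), 0), 0.5)
})

test_that("prob_dlt rejects bad inputs", {
  mp <- crm_model("power")
  expect_error(prob_dlt(mp, 0, 1.5), "0, 1")
  expect_error(prob_dlt(mp, c(0, 0), 0.5), "1 parameter")
  expect_error(prob_dlt(crm_model("logistic2"), 0.5, -1), "2 parameter")
})

test_that("prob_dlt is strictly increasing in the dose label", {
  cases <- list(
    list(m = crm_model("power"), p = 0.4, grid = seq(0.01, 0.99, length.out = 100)),
    list(m = crm_model("power", slope_link = "identity"), p = 2,
         grid = seq(0.01, 0.99, length.out = 100)),
    list(m = crm_model("logistic1"), p = 0.3, grid = seq(-8, 2, length.out = 100)),
    list(m = crm_model("logistic1", slope_link = "identity"), p = 1.7,
         grid = seq(-8, 2, length.out = 100)),
    list(m = crm_model("logistic2"), p = c(0.5, -0.2),
         grid = seq(-8, 2, length.out = 100)))
  for (cs in cases) {
    vals <- prob_dlt(cs$m, cs$p, cs$grid)
    expect_true(all(diff(vals) > 0), label = cs$m$family)
  }
})

test_that("dose labels invert the model exactly at the central parameter", {
  skel <- c(0.05, 0.10, 0.15, 0.33, 0.50)
  mp <- crm_model("power")
  expect_equal(dose_labels(mp, skel, 0), skel)  # Table-style reference

  m1 <- crm_model("logistic1", intercept = 3)
  lab <- dose_labels(m1, skel, 0)
  expect_equal(lab[4], log(0.33 / 0.67) - 3)
  expect_equal(round(lab[4], 4), -3.7082)
})

test_that("label construction round-trips through prob_dlt to < 1e-10", {
  set.seed(41)
  models <- list(crm_model("power"),
                 crm_model("logistic1", slope_link = "identity"),
                 crm_model("logistic1", intercept = 1.5),
                 crm_model("logistic2"))
  for (rep in seq_len(250)) {
    m <- models[[sample(length(models), 1)]]
    k <- sample(3:7, 1)
    skel <- sort(runif(k, 0.01, 0.9))
    if (any(diff(skel) < 1e-4)) next
    central <- if (m$n_params == 2) c(rnorm(1, 0, 0.5), rnorm(1, 0, 0.5)) else
      if (m$slope_link == "identity") rexp(1) + 0.1 else rnorm(1, 0, 0.7)
    lab <- dose_labels(m, skel, central)
    back <- vapply(lab, function(d) prob_dlt(m, central, d), numeric(1))
    expect_lt(max(abs(back - skel)), 1e-10)
  }
})

test_that("changing the logistic intercept moves the labels, not the fit", {
  skel <- c(0.05, 0.10, 0.15, 0.33, 0.50)
  lab3 <- dose_labels(crm_model("logistic1", intercept = 3), skel, 0)
  lab0 <- dose_labels(crm_model("logistic1", intercept = 0), skel, 0)
  expect_false(any(lab3 == lab0))
  back <- prob_dlt(crm_model("logistic1", intercept = 0), 0, lab0)
  expect_equal(back, skel, tolerance = 1e-12)
})

test_that("validate_skeleton reports validity, prior MTD and spacing", {
  rep1 <- validate_skeleton(c(0.05, 0.10, 0.15, 0.33, 0.50), ttl = 0.33)
  expect_true(rep1$valid)
  expect_identical(rep1$prior_mtd, 4L)

  rep2 <- validate_skeleton(c(0.2, 0.2, 0.3), ttl = 0.25)
  expect_false(rep2$valid)
  expect_match(paste(rep2$problems, collapse = " "), "increasing")

  rep3 <- validate_skeleton(c(0.1, 0.9), ttl = 0.25)
  expect_true(rep3$valid)
  expect_match(paste(rep3$warnings, collapse = " "), "within 0.15")
})

test_that("indifference-interval calibration pins the TTL and the interval", {
  sk <- skeleton_from_indifference(0.25, 0.05, prior_mtd_index = 3, k = 5,
                                   model = crm_model("power"))
  expect_equal(attr(sk, "indifference_interval"), c(0.20, 0.30))
  expect_equal(as.numeric(sk[3]), 0.25, tolerance = 1e-12)
  expect_true(validate_skeleton(as.numeric(sk), 0.25)$valid)

  # logistic variant pins the TTL too
  skl <- skeleton_from_indifference(0.25, 0.05, prior_mtd_index = 2, k = 4,
                                    model = crm_model("logistic1"))
  expect_equal(as.numeric(skl[2]), 0.25, tolerance = 1e-12)
  expect_true(all(diff(skl) > 0))
})

test_that("a narrower indifference interval gives a tighter skeleton", {
  gap <- function(hw) {
    sk <- skeleton_from_indifference(0.25, hw, prior_mtd_index = 3, k = 5,
                                     model = crm_model("power"))
    max(diff(as.numeric(sk)))
  }
  expect_lt(gap(0.03), gap(0.08))
})

test_that("degenerate panels and skeletons are rejected", {
  expect_error(dose_panel(c(2, 1), "mg"), "increasing")
  expect_error(dose_panel(5, "mg"), "two dose")
  expect_error(dose_panel(c(1, 2), ""), "non-empty")
  expect_error(dose_labels(crm_model("power"), c(0.3, 0.2), 0), "increasing")
  expect_error(dose_labels(crm_model("power"), c(0.1, 1.0), 0), "inside")
  expect_error(skeleton_from_indifference(0.25, 0.3, 2, 4), "halfwidth")
})
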