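test_that("build_analysis_dataset applies inclusion rules", {
  ps <- data.frame(
    participant_id = c("A", "A", "B", "C", "D"),
    measurement_date = as.Date(c("2004-05-01", "2006-05-01", "2005-01-01",
                                 "2005-01-01", "2005-01-01")),
    n_valid_days = 3L, mean_wear_minutes = 700,
    mean_sedentary_minutes = 300, mean_mpa_minutes = 40,
    mean_vpa_minutes = c(10, 11, 12, 13, 14))
  meta <- data.frame(
    participant_id = c("A", "B", "C"),
    study_id = "S1", region = "UK", age = c(9.5, 4.9, 18.0),
    sex = "male", ethnicity = "white", maternal_education = "high school",
    weight_status = "normal")

  ds <- build_analysis_dataset(ps, meta)
  # first measurement kept for A
  expect_identical(ds$vpa_min[ds$participant_id == "A"], 10)
  # age 4.9 excluded, age 18.0 inclusive
  expect_false("B" %in% ds$participant_id)
  expect_true("C" %in% ds$participant_id)
  # missing metadata reported, not silently dropped
  expect_identical(attr(ds, "missing_metadata"), "D")
  lg <- attr(ds, "log")
  expect_identical(unname(lg[c("summaries_in", "first_measurement",
                               "in_age_range")]),
                   c(5L, 4L, 2L))

  e <- build_analysis_dataset(ps[0, ], meta)
  expect_identical(nrow(e), 0L)
  expect_identical(unname(attr(e, "log")["summaries_in"]), 0L)
})

test_that("winsorize_p99 matches the order-statistic oracle", {
  # all equal: unchanged
  expect_equal(as.numeric(winsorize_p99(rep(7, 50))), rep(7, 50))

  x <- 1:100
  out <- winsorize_p99(x)
  q <- oracle_quantile(x, 0.99)
  expect_equal(attr(out, "threshold"), q)
  expect_equal(max(out), q)
  expect_equal(as.numeric(out[x <= q]), x[x <= q])

  # degenerate n = 2
  out2 <- winsorize_p99(c(0, 10))
  expect_equal(max(out2), oracle_quantile(c(0, 10), 0.99))

  expect_error(winsorize_p99(c(NA_real_, NA_real_)), "at least 2")

  # property: never increases a value, never touches values <= p99
  set.seed(3)
  for (k in 1:20) {
    x <- rlnorm(sample(10:200, 1), 2, 1)
    w <- winsorize_p99(x)
    expect_true(all(w <= x))
    q <- oracle_quantile(x, 0.99)
    expect_equal(as.numeric(w[x <= q]), x[x <= q])
  }
})

test_that("log_transform enforces its domain", {
  expect_identical(log_transform(1, 0), 0)
  expect_equal(log_transform(0, 0.5), log(0.5))
  expect_error(log_transform(0, 0), "zero_offset")
  expect_error(log_transform(-1), "negative")
})

test_that("fit_age_model recovers a noiseless generative slope exactly", {
  ds <- make_direct_dataset(n = 300, ratio = 0.931, sd_log = 0, seed = 2)
  # lm warns about the essentially perfect fit; that is the point here
  f <- suppressWarnings(fit_age_model(ds, "vpa", winsorize = FALSE,
                                      zero_offset = 0))
  expect_equal(f$beta_age, log(0.931), tolerance = 1e-6)
  expect_equal(f$ratio, 0.931, tolerance = 1e-6)

  # constant outcome: flat response
  ds$vpa_min <- 9
  f0 <- suppressWarnings(fit_age_model(ds, "vpa", winsorize = FALSE,
                                       zero_offset = 0))
  expect_equal(f0$beta_age, 0, tolerance = 1e-10)
  expect_equal(f0$ratio, 1, tolerance = 1e-10)

  # single distinct age is an error
  ds1 <- make_direct_dataset(n = 20, ages = rep(9, 20))
  expect_error(fit_age_model(ds1, "vpa"), "single distinct age")
})

test_that("fit_age_model matches a normal-equations oracle on a fixture", {
  ds <- make_direct_dataset(n = 30, sd_log = 0.4, seed = 7, n_studies = 3)
  f <- fit_age_model(ds, "vpa", winsorize = FALSE, zero_offset = 0.5)
  X <- cbind(1, ds$age, ds$wear_min,
             ds$study_id == "S2", ds$study_id == "S3")
  o <- oracle_ols(X, log(ds$vpa_min + 0.5))
  expect_equal(f$beta_age, o$beta[2], tolerance = 1e-8)
  expect_equal(f$se_beta, o$se[2], tolerance = 1e-8)
})

test_that("ratio_and_pct back-transforms are mutually consistent", {
  r <- ratio_and_pct(log(0.931), 0.00357)
  expect_equal(round(r$pct_change, 1), -6.9)
  expect_equal(r$pct_change, (r$ratio - 1) * 100)

  r0 <- ratio_and_pct(0, 0)
  expect_identical(c(r0$ratio, r0$pct_change), c(1, 0))
  expect_identical(r0$ratio_ci, c(1, 1))

  expect_equal(round(ratio_and_pct(log(1.065), 0.01)$pct_change, 1), 6.5)
  expect_error(ratio_and_pct(0.1, -1), "non-negative")

  # CI endpoints are the monotone transform of the beta CI
  set.seed(1)
  for (k in 1:20) {
    b <- rnorm(1); s <- rexp(1)
    r <- ratio_and_pct(b, s)
    expect_equal(r$ratio_ci, exp(b + c(-1, 1) * qnorm(0.975) * s))
    expect_equal(r$pct_ci, (r$ratio_ci - 1) * 100)
  }
})

test_that("test_interaction detects differing slopes and strata recover them", {
  set.seed(10)
  n <- 1200
  age <- runif(n, 5, 18)
  sex <- rep_len(c("male", "female"), n)
  r <- ifelse(sex == "male", 0.97, 0.89)
  ds <- data.frame(participant_id = sprintf("I%04d", 1:n), age = age,
                   vpa_min = 13 * r^(age - 5) * exp(rnorm(n, 0, 0.3)),
                   mpa_min = 40, wear_min = 770, sed_min = 349,
                   study_id = rep_len(c("S1", "S2"), n), sex = sex,
                   ethnicity = "white", maternal_education = "high school",
                   weight_status = "normal", region = "UK")
  ia <- test_interaction(ds, "sex", winsorize = FALSE, zero_offset = 0)
  expect_lt(ia$joint_p, 0.05)
  expect_true(ia$significant)
  expect_identical(ia$reference, "male")
  expect_equal(ia$stratified$male$ratio, 0.97, tolerance = 0.015)
  expect_equal(ia$stratified$female$ratio, 0.89, tolerance = 0.015)

  # identical slopes: interaction coefficient near 0
  ds2 <- ds
  ds2$vpa_min <- 13 * 0.93^(age - 5) * exp(rnorm(n, 0, 0.3))
  ia2 <- test_interaction(ds2, "sex", winsorize = FALSE, zero_offset = 0)
  b <- coef(ia2$fit)["age:modfemale"]
  expect_lt(abs(b), 0.01)

  # 4-level moderator: joint test on 3 degrees of freedom
  ds3 <- ds
  ds3$ethnicity <- rep_len(c("white", "black", "hispanic", "other"), n)
  ia3 <- test_interaction(ds3, "ethnicity", winsorize = FALSE, zero_offset = 0)
  expect_identical(ia3$joint_df, 3L)
  expect_length(ia3$per_level_p, 3)

  # single-level moderator errors
  expect_error(test_interaction(ds, "weight_status"), "single level")
})

test_that("age_band_check returns adjacent log differences", {
  # noiseless log-linear data: every full-width adjacent difference is
  # 2 ln r up to the deviation of each band's realized mean age from its
  # centre (absolute tolerance)
  ds <- make_direct_dataset(n = 4000, ratio = 0.9, sd_log = 0, seed = 4)
  bc <- age_band_check(ds, "vpa", winsorize = FALSE, zero_offset = 0)
  d <- bc$differences
  full <- d[1:5]               # [7,9)-[5,7) ... [15,17)-[13,15)
  expect_lt(max(abs(full - 2 * log(0.9))), 0.02)
  # terminal band is 1 year wide: expected 1.5 ln r between band centres
  expect_lt(abs(d[[6]] - 1.5 * log(0.9)), 0.02)

  # constant outcome: all differences zero
  dsc <- ds; dsc$vpa_min <- 5
  bcc <- age_band_check(dsc, "vpa", winsorize = FALSE, zero_offset = 0)
  expect_equal(unname(bcc$differences), rep(0, 6), tolerance = 1e-10)

  # empty band flagged missing
  dse <- ds[ds$age < 13 | ds$age >= 15, ]
  bce <- age_band_check(dse, "vpa", winsorize = FALSE, zero_offset = 0)
  expect_true(is.na(bce$coefficients[["[13,15)"]]))
  expect_true(any(is.na(bce$differences)))

  # band coefficients match an independently built dummy regression
  ds50 <- make_direct_dataset(n = 50, sd_log = 0.5, seed = 6, n_studies = 1)
  bc50 <- age_band_check(ds50, "vpa", winsorize = FALSE, zero_offset = 0)
  band <- droplevels(cut(ds50$age, c(5, 7, 9, 11, 13, 15, 17, 18),
                         right = FALSE, include.lowest = TRUE))
  X <- cbind(stats::model.matrix(~ band), wear = ds50$wear_min)
  o <- oracle_ols(X, log(ds50$vpa_min))
  got <- bc50$coefficients[levels(band)][-1]
  expect_equal(unname(got), unname(o$beta[2:nlevels(band)]), tolerance = 1e-8)
})

test_that("leave_one_study_out refits per study and flags sign changes", {
  set.seed(5)
  n <- 400
  age <- runif(n, 5, 18)
  study <- rep_len(c("S-up", "S-down"), n)
  r <- ifelse(study == "S-up", 1.08, 0.85)
  ds <- data.frame(participant_id = sprintf("L%04d", 1:n), age = age,
                   vpa_min = 12 * r^(age - 5) * exp(rnorm(n, 0, 0.2)),
                   mpa_min = 40, wear_min = 770, sed_min = 349,
                   study_id = study, sex = "male", ethnicity = "white",
                   maternal_education = "high school",
                   weight_status = "normal",
                   region = ifelse(study == "S-up", "UK", "Europe"))
  lo <- leave_one_study_out(ds, "vpa", winsorize = FALSE, zero_offset = 0)
  expect_length(lo$by_study, 2)
  # omitting the downward study leaves the upward trend and vice versa
  expect_gt(lo$by_study[["S-down"]]$beta_age, 0)
  expect_lt(lo$by_study[["S-up"]]$beta_age, 0)
  expect_true(any(lo$sign_flip))

  # homogeneous studies: every refit stays inside the full fit's CI
  ds2 <- make_direct_dataset(n = 900, ratio = 0.93, sd_log = 0.3, seed = 8,
                             n_studies = 3)
  lo2 <- leave_one_study_out(ds2, "vpa", winsorize = FALSE, zero_offset = 0)
  expect_length(lo2$by_study, 3)
  expect_false(any(lo2$sign_flip))
  for (f in lo2$by_study)
    expect_true(f$ratio >= lo2$full$ratio_ci[1] &&
                f$ratio <= lo2$full$ratio_ci[2])

  expect_error(leave_one_study_out(make_direct_dataset(n = 20, n_studies = 1)),
               "at least 2 studies")
})
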