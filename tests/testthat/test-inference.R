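test_that("single-term Wald statistic equals the squared z ratio", {
  coh <- small_cohort(seed = 14, n = 12)
  fit <- fit_random_intercept(coh$patients, coh$samples,
                              lipid_design("tc", c("storage_time",
                                                   "followup_time")))
  tt <- wald_test(fit, "storage_time")
  expect_equal(tt$statistic,
               (coef(fit)["storage_time"] / fit$se["storage_time"])^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tt$df, 1)
  # a zeroed coefficient gives statistic 0 and p = 1
  fit0 <- fit
  fit0$coefficients["storage_time"] <- 0
  t0 <- wald_test(fit0, "storage_time")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
})

test_that("Wald test rejects empty or unknown term sets", {
  coh <- small_cohort(seed = 14, n = 6)
  fit <- fit_random_intercept(coh$patients, coh$samples,
                              lipid_design("tc", "followup_time"))
  expect_error(wald_test(fit, character()), "empty")
  expect_error(wald_test(fit, "nonexistent"), "not in fit")
})

test_that("likelihood-ratio test: identity, non-negativity, REML guard", {
  coh <- small_cohort(seed = 15, n = 15)
  des_full <- lipid_design("tc", c("storage_time", "followup_time", "age"))
  des_red <- lipid_design("tc", c("followup_time", "age"))
  full <- fit_random_intercept(coh$patients, coh$samples, des_full, "ML")
  red <- fit_random_intercept(coh$patients, coh$samples, des_red, "ML")
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  nested <- lr_test(full, red)
  expect_gte(nested$statistic, 0)
  expect_equal(nested$df, 1)
  full_reml <- fit_random_intercept(coh$patients, coh$samples, des_full, "REML")
  expect_error(lr_test(full_reml, red), "REML")
})

test_that("Wald and LRT p-values agree asymptotically for one degree of freedom", {
  # large balanced cohort so both tests are in their asymptotic regime
  set.seed(77)
  m <- 800; k <- 3
  ids <- sprintf("P%04d", seq_len(m))
  x_pat <- c(0, 1, 2)
  b <- stats::rnorm(m, 0, 0.5)
  xp <- stats::rnorm(m)  # patient-level covariate with a weak effect
  y <- 2 + 0.03 * rep(xp, each = k) + 0.1 * rep(x_pat, m) +
    rep(b, each = k) + stats::rnorm(m * k, 0, 0.4)
  patients <- data.frame(patient_id = ids, subcohort = 1,
                         inclusion_date = 2000, age = 50 + xp, sex = "male",
                         bmi = 25, smoker = FALSE, statin = FALSE,
                         gluco = FALSE, das28 = 5, rf_positive = TRUE,
                         sbp = 130)
  samples <- data.frame(patient_id = rep(ids, each = k),
                        followup_time = rep(x_pat, m), sample_date = 2000,
                        storage_time = 1, tc_obs = y, hdl_obs = 1,
                        tg_obs = 1, sbp = 130)
  full <- fit_random_intercept(patients, samples,
                               lipid_design("tc", c("followup_time", "age")),
                               "ML")
  red <- fit_random_intercept(patients, samples,
                              lipid_design("tc", "followup_time"), "ML")
  p_wald <- wald_test(full, "age")$p_value
  p_lrt <- lr_test(full, red)$p_value
  expect_lt(abs(p_wald - p_lrt), 0.01)
})

test_that("a pure-noise candidate is not flagged as a confounder", {
  # patient-level noise covariate, independent of storage and lipid
  selected_count <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    coh <- small_cohort(seed = 500 + i, n = 20)
    set.seed(9000 + i)
    coh$patients$das28 <- stats::rnorm(nrow(coh$patients), 5, 1)
    des <- lipid_design("tc", c("storage_time", "followup_time",
                                "followup_time_sq"))
    sel <- screen_confounders(coh$patients, coh$samples, des, "das28")
    if ("das28" %in% sel) selected_count <- selected_count + 1
  }
  expect_lte(selected_count / reps, 0.1)
})

test_that("a planted storage-correlated covariate is flagged as a confounder", {
  coh <- small_cohort(seed = 55, n = 30)
  pt <- coh$patients; sm <- coh$samples
  # das28 tracks inclusion date (hence storage) and directly shifts TC;
  # jittered so it is correlated with, not collinear to, storage time
  set.seed(56)
  pt$das28 <- 5 + 0.2 * (2012 - pt$inclusion_date) +
    stats::rnorm(nrow(pt), 0, 0.3)
  sm$tc_obs <- sm$tc_obs + 0.4 * pt$das28[match(sm$patient_id, pt$patient_id)]
  des <- lipid_design("tc", c("storage_time", "followup_time",
                              "followup_time_sq"))
  sel <- screen_confounders(pt, sm, des, c("das28"))
  expect_true("das28" %in% sel)
  details <- attr(sel, "details")
  expect_gt(details$max_rel_change[details$candidate == "das28"], 0.10)
})

test_that("the confounder screen is deterministic and rejects overlap", {
  coh <- small_cohort(seed = 66, n = 10)
  des <- lipid_design("tc", c("storage_time", "followup_time"))
  s1 <- screen_confounders(coh$patients, coh$samples, des, c("age", "sex"))
  s2 <- screen_confounders(coh$patients, coh$samples, des, c("age", "sex"))
  expect_identical(attr(s1, "details"), attr(s2, "details"))
  expect_error(screen_confounders(coh$patients, coh$samples, des,
                                  c("storage_time")), "already in the design")
})

test_that("period-effect test validates the subcohort structure", {
  coh <- small_cohort(seed = 18, n = 10)
  one <- coh$patients$subcohort == 1
  expect_error(period_effect_test(coh$patients[one, ],
                                  coh$samples[coh$samples$patient_id %in%
                                                coh$patients$patient_id[one], ],
                                  "tc"),
               "at least 2 subcohorts")
  # collapse subcohort 1 to a single follow-up time
  sm <- coh$samples
  in1 <- sm$patient_id %in% coh$patients$patient_id[one]
  sm <- sm[!in1 | sm$followup_time == 0, ]
  expect_error(period_effect_test(coh$patients, sm, "tc"),
               "single follow-up time.*1")
})

test_that("period-effect test has power against a planted slope difference", {
  hits <- 0
  reps <- 25
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(seed = 700 + i,
                                         true_decay_tc = 0,
                                         true_decay_hdl = 0))
    pt <- coh$patients; sm <- coh$samples
    in5 <- sm$patient_id %in% pt$patient_id[pt$subcohort == 5]
    sm$tc_obs[in5] <- sm$tc_obs[in5] + 0.15 * sm$followup_time[in5]
    if (period_effect_test(pt, sm, "tc")$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.8)
})
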