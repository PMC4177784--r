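test_that("REML on a balanced one-way layout equals the ANOVA closed form", {
  ow <- make_oneway(m = 12, k = 5, seed = 42)
  fit <- fit_random_intercept(ow$patients, ow$samples, lipid_design("tc"),
                              method = "REML")
  an <- oneway_anova(ow$y, 12, 5)
  expect_equal(fit$sigma2_e, an$sigma2_e, tolerance = 1e-10)
  expect_equal(fit$sigma2_b, an$sigma2_b, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), mean(ow$y), tolerance = 1e-10)
})

test_that("with no between-patient variance the fit collapses to pooled OLS", {
  set.seed(8)
  m <- 40; k <- 4
  ids <- sprintf("P%03d", seq_len(m))
  x <- rep(c(0, 1, 2, 3), m)
  y <- 1 + 0.5 * x + stats::rnorm(m * k, 0, 0.3)  # sigma_b = 0 truth
  patients <- data.frame(patient_id = ids, subcohort = 1,
                         inclusion_date = 2000, age = 50, sex = "male",
                         bmi = 25, smoker = FALSE, statin = FALSE,
                         gluco = FALSE, das28 = 5, rf_positive = TRUE,
                         sbp = 130)
  samples <- data.frame(patient_id = rep(ids, each = k), followup_time = x,
                        sample_date = 2000, storage_time = 1, tc_obs = y,
                        hdl_obs = 1, tg_obs = 1, sbp = 130)
  fit <- fit_random_intercept(patients, samples,
                              lipid_design("tc", "followup_time"), "REML")
  ols <- stats::lm(y ~ x)
  if (fit$sigma2_b < 1e-10) {
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  } else {
    # shrinkage is active; estimates still agree loosely
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-2)
  }
})

test_that("fixed effects equal the closed-form GLS solution at the fitted variances", {
  coh <- small_cohort(seed = 21, n = 12)
  des <- lipid_design("tc", c("storage_time", "followup_time",
                              "followup_time_sq", "age", "sex"))
  fit <- fit_random_intercept(coh$patients, coh$samples, des, "REML")
  dat <- lme4_frame(coh)
  X <- stats::model.matrix(~ storage_time + followup_time + followup_time_sq +
                             age + sex, dat)
  y <- dat$tc_obs
  g <- factor(dat$patient_id)
  # dense block compound-symmetric covariance, inverted directly
  Z <- stats::model.matrix(~ g - 1)
  V <- fit$sigma2_b * tcrossprod(Z) + fit$sigma2_e * diag(length(y))
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(coef(fit)), unname(drop(beta_gls)), tolerance = 1e-8)
})

test_that("estimates, SEs and likelihoods agree with lme4", {
  skip_if_not_installed("lme4")
  coh <- small_cohort(seed = 11, n = 30)
  dat <- lme4_frame(coh)
  des <- lipid_design("tc", c("storage_time", "followup_time",
                              "followup_time_sq", "age", "sex", "bmi",
                              "statin", "gluco"))
  for (reml in c(TRUE, FALSE)) {
    fit <- fit_random_intercept(coh$patients, coh$samples, des,
                                if (reml) "REML" else "ML")
    m <- lme4::lmer(tc_obs ~ storage_time + followup_time + followup_time_sq +
                      age + sex + bmi + statin + gluco + (1 | patient_id),
                    dat, REML = reml)
    expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(as.matrix(vcov(m))))), tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(fit$sigma2_b, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
    expect_equal(fit$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  }
})

test_that("an orthogonal added column leaves existing estimates unchanged", {
  # within-patient patterns: z orthogonal to intercept, trend and the
  # fixed 'residual' pattern, with zero patient sums, so the weighted
  # cross-products vanish for every lambda
  m <- 10; k <- 4
  x_pat <- c(0, 1, 2, 3)
  z_pat <- c(1, -1, -1, 1)
  e_pat <- c(1, 1, -1, -1) * 0.3
  set.seed(13)
  b <- stats::rnorm(m, 0, 0.6)
  y <- 2 + 0.4 * rep(x_pat, m) + rep(b, each = k) + rep(e_pat, m)
  ow <- make_oneway(m = m, k = k, y = y)
  ow$samples$followup_time <- rep(x_pat, m)
  ow$samples$das28 <- rep(z_pat, m)
  base <- fit_random_intercept(ow$patients[, setdiff(names(ow$patients), "das28")],
                               ow$samples, lipid_design("tc", "followup_time"),
                               "ML")
  aug <- fit_random_intercept(ow$patients[, setdiff(names(ow$patients), "das28")],
                              ow$samples,
                              lipid_design("tc", c("followup_time", "das28")),
                              "ML")
  expect_equal(coef(aug)[names(coef(base))], coef(base), tolerance = 1e-10)
})

test_that("ML and REML fixed effects coincide on balanced designs", {
  ow <- make_oneway(m = 15, k = 6, seed = 9)
  ow$samples$followup_time <- rep(0:5, 15)
  des <- lipid_design("tc", "followup_time")
  f_ml <- fit_random_intercept(ow$patients, ow$samples, des, "ML")
  f_reml <- fit_random_intercept(ow$patients, ow$samples, des, "REML")
  expect_equal(coef(f_ml), coef(f_reml), tolerance = 1e-6)
})

test_that("rank-deficient designs fail naming the collinear term", {
  ow <- make_oneway(m = 8, k = 3, seed = 10)
  # storage_time is constant -> collinear with the intercept
  expect_error(fit_random_intercept(ow$patients, ow$samples,
                                    lipid_design("tc", "storage_time")),
               "storage_time")
})

test_that("design invariants are enforced", {
  expect_error(lipid_design("tc", c("followup_time_sq")), "followup_time")
  expect_error(lipid_design("tc", c("subcohort:followup_time", "subcohort")),
               "main effects")
  expect_error(lipid_design("tc", c("age", "age")), "duplicated")
})

test_that("the storage-time coefficient recovers the configured decay", {
  coh <- generate_cohort(cohort_config(seed = 31))
  fit <- fit_random_intercept(
    coh$patients, coh$samples,
    lipid_design("tc", c("storage_time", "followup_time", "followup_time_sq",
                         "age", "sex", "bmi", "statin", "gluco")), "ML")
  est <- coef(fit)["storage_time"]
  se <- fit$se["storage_time"]
  expect_lt(est, 0)
  expect_lt(abs(est - (-0.030)), 3 * se)
})
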