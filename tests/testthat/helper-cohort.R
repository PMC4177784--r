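# shared fixture builders (all data generated in code)

small_cohort <- function(seed = 1, n = 10, ...) {
  generate_cohort(cohort_config(n_patients_per_subcohort = n, seed = seed, ...))
}

# balanced one-way layout: m patients x k replicates, no real covariate
# structure (constant patient table), optional fixed y override
make_oneway <- function(m = 12, k = 5, mu = 2, sd_b = 0.7, sd_e = 0.4,
                        seed = 42, y = NULL) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(m))
  if (is.null(y))
    y <- mu + rep(stats::rnorm(m, 0, sd_b), each = k) +
      stats::rnorm(m * k, 0, sd_e)
  patients <- data.frame(
    patient_id = ids, subcohort = 1, inclusion_date = 2000, age = 50,
    sex = "male", bmi = 25, smoker = FALSE, statin = FALSE, gluco = FALSE,
    das28 = 5, rf_positive = TRUE, sbp = 130, stringsAsFactors = FALSE)
  samples <- data.frame(
    patient_id = rep(ids, each = k), followup_time = rep(seq_len(k) - 1, m),
    sample_date = 2000, storage_time = 1, tc_obs = y, hdl_obs = 1,
    tg_obs = 1, sbp = 130, stringsAsFactors = FALSE)
  list(patients = patients, samples = samples, y = y, ids = ids)
}

# closed-form one-way ANOVA / REML estimators for the balanced layout
oneway_anova <- function(y, m, k) {
  gm <- tapply(y, rep(seq_len(m), each = k), mean)
  msb <- k * sum((gm - mean(y))^2) / (m - 1)
  msw <- sum((y - rep(gm, each = k))^2) / (m * (k - 1))
  list(msb = msb, msw = msw, sigma2_e = msw, sigma2_b = (msb - msw) / k)
}

# model frame with the factor coding fit_random_intercept uses internally
lme4_frame <- function(coh) {
  dat <- merge(coh$samples, coh$patients, by = "patient_id")
  dat$followup_time_sq <- dat$followup_time^2
  dat$sex <- factor(dat$sex, levels = c("male", "female"))
  dat$subcohort <- factor(dat$subcohort)
  dat
}
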