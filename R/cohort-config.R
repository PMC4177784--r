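#' Default per-subcohort covariate parameters
#'
#' Means/SDs and prevalences of the baseline covariates for each of the five
#' inclusion-period subcohorts (1985--1989 ... 2005--2009) of a
#' rheumatoid-arthritis inception cohort with the secular trends such a
#' cohort shows: rising statin and glucocorticoid use, falling smoking,
#' rising age at inclusion.
#'
#' @return A data.frame with one row per subcohort and columns
#'   `age_mean`, `age_sd`, `prop_female`, `prop_rf`, `das28_mean`,
#'   `das28_sd`, `bmi_mean`, `bmi_sd`, `prop_smoker`, `prop_statin`,
#'   `prop_gluco`.
#' @export
default_covariate_params <- function() {
  data.frame(
    subcohort   = 1:5,
    age_mean    = c(51, 50, 52, 58, 59),
    age_sd      = c(14.4, 13.5, 14.5, 12.1, 12.6),
    prop_female = c(0.533, 0.613, 0.567, 0.833, 0.677),
    prop_rf     = c(0.867, 0.742, 0.833, 0.767, 0.806),
    das28_mean  = c(5.6, 5.3, 4.8, 4.9, 5.0),
    das28_sd    = c(1.2, 1.4, 1.6, 1.0, 1.2),
    bmi_mean    = c(26.0, 27.1, 25.6, 26.2, 26.6),
    bmi_sd      = c(3.8, 4.6, 3.3, 3.0, 6.8),
    prop_smoker = c(0.467, 0.194, 0.333, 0.300, 0.290),
    prop_statin = c(0.000, 0.000, 0.067, 0.067, 0.290),
    prop_gluco  = c(0.100, 0.097, 0.167, 0.567, 0.548)
  )
}

#' Configure a synthetic inception cohort
#'
#' Builds and validates the configuration driving [generate_cohort()]. The
#' defaults emulate a five-subcohort inception cohort enrolled 1985--2009,
#' sampled at follow-up years 0, 1, 2, 3, 5, 7 and 10, with all samples
#' assayed at one fixed analysis date (January 2012) so that storage time is
#' confounded with inclusion period by design. Observed lipids follow the
#' same functional form the longitudinal model fits: fixed covariate
#' effects, a quadratic follow-up trend, a patient-level random intercept,
#' a linear per-storage-year decay and Gaussian residual noise.
#'
#' Fixed-effect truth defaults (intercepts, follow-up trend, covariate
#' effects, decay slopes) are the estimates an adjusted random-intercept
#' model reports on such data: TC decays 0.030 mmol/L and HDL-c
#' 0.024 mmol/L per storage year. Noise defaults are per lipid: the TC
#' scale (around 5 mmol/L) carries sigma_b = 0.8 / sigma_e = 0.5, while the
#' HDL-c scale (around 1.2 mmol/L) carries sigma_b = 0.25 /
#' sigma_e = 0.15 so that the positivity floor is essentially never hit and
#' decay recovery is unbiased.
#'
#' @param n_patients_per_subcohort patients per subcohort (default 30).
#' @param subcohort_periods list of `c(start_year, end_year)` inclusive
#'   calendar-year pairs; must be disjoint and ordered.
#' @param followup_years sampling times in years since inclusion, sorted.
#' @param analysis_date decimal year all samples are assayed (default 2012).
#' @param true_decay_tc,true_decay_hdl linear decay, mmol/L per storage year.
#' @param followup_trend_tc,followup_trend_hdl numeric `c(g1, g2)`:
#'   linear and quadratic within-patient follow-up coefficients.
#' @param beta_tc,beta_hdl named numeric vectors of fixed-effect truth:
#'   `intercept`, and per-covariate effects (`age`, `sexmale`/`sexfemale`
#'   convention: effect of female sex is `sexfemale`), see defaults.
#' @param random_intercept_sd_tc,random_intercept_sd_hdl patient-level SD, mmol/L.
#' @param residual_sd_tc,residual_sd_hdl residual SD, mmol/L.
#' @param covariate_params per-subcohort covariate distributions, as
#'   [default_covariate_params()].
#' @param sbp_mean,sbp_sd systolic blood pressure distribution (mmHg),
#'   generated because the risk model needs it.
#' @param tg_meanlog,tg_sdlog log-normal triglyceride parameters (mmol/L).
#' @param lipid_floor positivity floor (mmol/L); observed lipids below it
#'   are resampled.
#' @param seed integer seed driving all randomness of one cohort draw.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_patients_per_subcohort = 10, seed = 1)
#' cfg$true_decay_tc
#' @export
cohort_config <- function(n_patients_per_subcohort = 30,
                          subcohort_periods = list(c(1985, 1989), c(1990, 1994),
                                                   c(1995, 1999), c(2000, 2004),
                                                   c(2005, 2009)),
                          followup_years = c(0, 1, 2, 3, 5, 7, 10),
                          analysis_date = 2012.0,
                          true_decay_tc = 0.030,
                          true_decay_hdl = 0.024,
                          followup_trend_tc = c(0.012, -0.0001),
                          followup_trend_hdl = c(0.003, -0.00003),
                          beta_tc = c(intercept = 3.408, age = 0.016,
                                      sexfemale = 0.023, bmi = 0.011,
                                      statin = 0.888, gluco = 0.239),
                          beta_hdl = c(intercept = 1.247, age = 0.003,
                                       sexfemale = -0.074),
                          random_intercept_sd_tc = 0.8,
                          residual_sd_tc = 0.5,
                          random_intercept_sd_hdl = 0.25,
                          residual_sd_hdl = 0.15,
                          covariate_params = default_covariate_params(),
                          sbp_mean = 135, sbp_sd = 15,
                          tg_meanlog = 0.45, tg_sdlog = 0.35,
                          lipid_floor = 0.1,
                          seed = 1L) {
  cfg <- list(
    n_patients_per_subcohort = n_patients_per_subcohort,
    subcohort_periods = subcohort_periods,
    followup_years = followup_years,
    analysis_date = analysis_date,
    true_decay_tc = true_decay_tc,
    true_decay_hdl = true_decay_hdl,
    followup_trend_tc = followup_trend_tc,
    followup_trend_hdl = followup_trend_hdl,
    beta_tc = beta_tc,
    beta_hdl = beta_hdl,
    random_intercept_sd_tc = random_intercept_sd_tc,
    residual_sd_tc = residual_sd_tc,
    random_intercept_sd_hdl = random_intercept_sd_hdl,
    residual_sd_hdl = residual_sd_hdl,
    covariate_params = covariate_params,
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    tg_meanlog = tg_meanlog, tg_sdlog = tg_sdlog,
    lipid_floor = lipid_floor,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is_number(cfg$n_patients_per_subcohort) || cfg$n_patients_per_subcohort < 1)
    stop_field("n_patients_per_subcohort", "must be a positive integer")
  per <- cfg$subcohort_periods
  if (!is.list(per) || !length(per) || !all(vapply(per, length, 1L) == 2L))
    stop_field("subcohort_periods", "must be a list of (start, end) pairs")
  starts <- vapply(per, `[`, numeric(1), 1)
  ends <- vapply(per, `[`, numeric(1), 2)
  if (any(ends < starts))
    stop_field("subcohort_periods", "period end before start")
  if (length(per) > 1 && any(starts[-1] <= ends[-length(ends)]))
    stop_field("subcohort_periods", "periods must be disjoint and ordered")
  fy <- cfg$followup_years
  if (any(fy < 0) || is.unsorted(fy, strictly = TRUE))
    stop_field("followup_years", "must be non-negative and strictly increasing")
  for (f in c("true_decay_tc", "true_decay_hdl")) {
    if (!is_number(cfg[[f]])) stop_field(f, "must be a finite number")
  }
  for (f in c("random_intercept_sd_tc", "residual_sd_tc",
              "random_intercept_sd_hdl", "residual_sd_hdl",
              "sbp_sd", "tg_sdlog", "lipid_floor")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0)
      stop_field(f, "must be a non-negative number")
  }
  # latest possible sampling date is end of last period + last follow-up;
  # samples beyond analysis_date are censored, but the analysis date cannot
  # precede the earliest inclusion
  if (cfg$analysis_date < starts[1])
    stop_field("analysis_date", "precedes the first inclusion period")
  cp <- cfg$covariate_params
  need <- c("age_mean", "age_sd", "prop_female", "prop_rf", "das28_mean",
            "das28_sd", "bmi_mean", "bmi_sd", "prop_smoker", "prop_statin",
            "prop_gluco")
  if (!is.data.frame(cp) || nrow(cp) != length(per) || !all(need %in% names(cp)))
    stop_field("covariate_params",
               sprintf("must be a data.frame with %d rows and columns %s",
                       length(per), paste(need, collapse = ", ")))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic inception cohort configuration\n")
  cat(sprintf("  %d subcohorts x %d patients; follow-up years: %s\n",
              length(x$subcohort_periods), x$n_patients_per_subcohort,
              paste(x$followup_years, collapse = ", ")))
  cat(sprintf("  analysis date %.1f; decay TC %.3f, HDL %.3f mmol/L per year\n",
              x$analysis_date, x$true_decay_tc, x$true_decay_hdl))
  cat(sprintf("  noise (sigma_b/sigma_e): TC %.2f/%.2f, HDL %.2f/%.2f; seed %d\n",
              x$random_intercept_sd_tc, x$residual_sd_tc,
              x$random_intercept_sd_hdl, x$residual_sd_hdl, x$seed))
  invisible(x)
}

#' Storage time of a sample
#'
#' Years a sample has spent frozen: the analysis date minus the date the
#' sample was drawn (and first frozen).
#'
#' @param sample_date decimal year the sample was drawn.
#' @param analysis_date decimal year the sample was assayed.
#' @return storage time in years (vectorized).
#' @examples
#' storage_years(2002.0, 2012.0)  # 10
#' @export
storage_years <- function(sample_date, analysis_date) {
  out <- analysis_date - sample_date
  if (any(out < 0))
    stop("sample analysed before it was taken (negative storage time)",
         call. = FALSE)
  out
}
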