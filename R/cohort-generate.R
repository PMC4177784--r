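#' Generate a synthetic inception cohort
#'
#' Draws patients and their repeated serum samples under the configuration
#' from [cohort_config()]. Inclusion dates are uniform within each
#' subcohort's calendar period; each patient is sampled at every configured
#' follow-up year whose date does not exceed the analysis date (so recent
#' subcohorts have truncated follow-up — the staircase design). The
#' observed lipid value of patient \eqn{i} at follow-up time \eqn{t_f} is
#' \deqn{y = \beta_0 + x_i'\beta + \gamma_1 t_f + \gamma_2 t_f^2 + b_i
#'       - \delta \, t_s + \varepsilon,}
#' with \eqn{b_i \sim N(0, \sigma_b^2)}, \eqn{\varepsilon \sim N(0,
#' \sigma_e^2)}, storage time \eqn{t_s} = analysis date − sample date and
#' decay rate \eqn{\delta} per lipid. Residuals are resampled when a value
#' would fall below the positivity floor.
#'
#' @param config a [cohort_config()] object.
#' @param keep_latent keep generator-only fields (`tc_true`, `hdl_true`,
#'   patient random intercepts)? Default `TRUE`; they are dropped when
#'   writing analysis CSVs.
#' @return A list with class `lipid_cohort`: `patients` (one row per
#'   patient: `patient_id`, `subcohort`, `inclusion_date`, `age`, `sex`,
#'   `bmi`, `smoker`, `statin`, `gluco`, `das28`, `rf_positive`, `sbp`) and
#'   `samples` (one row per measurement occasion: `patient_id`,
#'   `followup_time`, `sample_date`, `storage_time`, `tc_obs`, `hdl_obs`,
#'   `tg_obs`, `sbp`). Deterministic given `config$seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients_per_subcohort = 5, seed = 7))
#' nrow(coh$patients)
#' range(coh$samples$storage_time)
#' @export
generate_cohort <- function(config, keep_latent = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)

  nsc <- length(config$subcohort_periods)
  npp <- config$n_patients_per_subcohort
  n <- nsc * npp
  cp <- config$covariate_params

  subcohort <- rep(seq_len(nsc), each = npp)
  starts <- vapply(config$subcohort_periods, `[`, numeric(1), 1)
  ends <- vapply(config$subcohort_periods, `[`, numeric(1), 2)
  # inclusive calendar years: uniform over [start, end + 1)
  inclusion_date <- stats::runif(n, starts[subcohort], ends[subcohort] + 1)
  inclusion_date <- pmin(inclusion_date, config$analysis_date)

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    subcohort = subcohort,
    inclusion_date = inclusion_date,
    age = round(rnorm_trunc(n, cp$age_mean[subcohort], cp$age_sd[subcohort],
                            18, 95)),
    sex = ifelse(stats::runif(n) < cp$prop_female[subcohort],
                 "female", "male"),
    bmi = rnorm_trunc(n, cp$bmi_mean[subcohort], cp$bmi_sd[subcohort], 15, 60),
    smoker = stats::runif(n) < cp$prop_smoker[subcohort],
    statin = stats::runif(n) < cp$prop_statin[subcohort],
    gluco = stats::runif(n) < cp$prop_gluco[subcohort],
    das28 = rnorm_trunc(n, cp$das28_mean[subcohort], cp$das28_sd[subcohort],
                        0, 10),
    rf_positive = stats::runif(n) < cp$prop_rf[subcohort],
    sbp = rnorm_trunc(n, config$sbp_mean, config$sbp_sd, 70, 260),
    stringsAsFactors = FALSE
  )
  b_tc <- stats::rnorm(n, 0, config$random_intercept_sd_tc)
  b_hdl <- stats::rnorm(n, 0, config$random_intercept_sd_hdl)

  # expand to the sampling grid, censor at the analysis date
  fy <- config$followup_years
  idx <- rep(seq_len(n), each = length(fy))
  ft <- rep(fy, times = n)
  sample_date <- patients$inclusion_date[idx] + ft
  keep <- sample_date <= config$analysis_date
  idx <- idx[keep]; ft <- ft[keep]; sample_date <- sample_date[keep]
  st <- storage_years(sample_date, config$analysis_date)

  fixed_part <- function(beta, trend) {
    out <- beta[["intercept"]] +
      trend[1] * ft + trend[2] * ft^2
    covs <- setdiff(names(beta), "intercept")
    for (cv in covs) {
      x <- switch(cv,
        sexfemale = as.numeric(patients$sex[idx] == "female"),
        age = patients$age[idx],
        bmi = patients$bmi[idx],
        statin = as.numeric(patients$statin[idx]),
        gluco = as.numeric(patients$gluco[idx]),
        das28 = patients$das28[idx],
        rf_positive = as.numeric(patients$rf_positive[idx]),
        smoker = as.numeric(patients$smoker[idx]),
        stop_field(paste0("beta$", cv), "unknown covariate effect")
      )
      out <- out + beta[[cv]] * x
    }
    out
  }

  observe <- function(true_level, decay, res_sd) {
    m <- length(true_level)
    mean_obs <- true_level - decay * st
    if (res_sd > 0) {
      obs <- rnorm_trunc(m, mean_obs, res_sd, lower = config$lipid_floor)
    } else {
      obs <- pmax(mean_obs, config$lipid_floor)
    }
    obs
  }

  tc_true <- fixed_part(config$beta_tc, config$followup_trend_tc) + b_tc[idx]
  hdl_true <- fixed_part(config$beta_hdl, config$followup_trend_hdl) + b_hdl[idx]

  samples <- data.frame(
    patient_id = patients$patient_id[idx],
    followup_time = ft,
    sample_date = sample_date,
    storage_time = st,
    tc_obs = observe(tc_true, config$true_decay_tc, config$residual_sd_tc),
    hdl_obs = observe(hdl_true, config$true_decay_hdl, config$residual_sd_hdl),
    tg_obs = stats::rlnorm(length(idx), config$tg_meanlog, config$tg_sdlog),
    sbp = patients$sbp[idx],
    stringsAsFactors = FALSE
  )
  if (keep_latent) {
    samples$tc_true <- tc_true
    samples$hdl_true <- hdl_true
    patients$random_intercept_tc <- b_tc
    patients$random_intercept_hdl <- b_hdl
  }
  structure(list(patients = patients, samples = samples, config = config),
            class = "lipid_cohort")
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic lipid cohort: %d patients, %d samples, storage %.1f-%.1f years\n",
    nrow(x$patients), nrow(x$samples),
    min(x$samples$storage_time), max(x$samples$storage_time)))
  invisible(x)
}
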