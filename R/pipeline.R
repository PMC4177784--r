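## end-to-end pipeline and CSV I/O

required_patient_cols <- c("patient_id", "subcohort", "inclusion_date", "age",
                           "sex", "bmi", "smoker", "statin", "gluco", "das28",
                           "rf_positive", "sbp")
required_sample_cols <- c("patient_id", "followup_time", "sample_date",
                          "storage_time", "tc_obs", "hdl_obs")

#' Write a cohort as patients/samples CSV files
#'
#' Writes `patients.csv` and `samples.csv` in the package's documented
#' dialect: comma-separated, UTF-8, `.` decimal, decimal-year dates,
#' 12-significant-digit numerics, optional `#`-prefixed comment header
#' lines. Latent generator fields (`tc_true`, `hdl_true`, random
#' intercepts) are dropped.
#'
#' @param cohort a [generate_cohort()] result (or a list with `patients`
#'   and `samples` data.frames).
#' @param dir output directory (created if needed).
#' @param header_lines comment lines written above each header.
#' @return named character vector of the two paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, header_lines = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- cohort$patients
  sm <- cohort$samples
  pt <- pt[, setdiff(names(pt), c("random_intercept_tc", "random_intercept_hdl")),
           drop = FALSE]
  sm <- sm[, setdiff(names(sm), c("tc_true", "hdl_true")), drop = FALSE]
  paths <- c(patients = file.path(dir, "patients.csv"),
             samples = file.path(dir, "samples.csv"))
  for (nm in names(paths)) {
    df <- if (nm == "patients") pt else sm
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    con <- file(paths[[nm]], "w")
    if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

check_numeric_col <- function(df, col, file) {
  x <- df[[col]]
  if (is.numeric(x)) return(invisible())
  parsed <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(parsed) & !is.na(x) & x != "")
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' of %s (data row %d: '%s')",
                 col, file, bad[1], x[bad[1]]), call. = FALSE)
  invisible()
}

#' Read a cohort from patients/samples CSV files
#'
#' Reads the dialect written by [write_cohort_csv()]. Required columns are
#' checked by name; unknown columns are preserved untouched. Non-numeric
#' values in lipid/date columns raise an error naming the column and row.
#'
#' @param patients_path,samples_path CSV paths.
#' @return list with `patients` and `samples` data.frames.
#' @export
read_cohort_csv <- function(patients_path, samples_path) {
  pt <- utils::read.csv(patients_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  sm <- utils::read.csv(samples_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  miss_p <- setdiff(required_patient_cols, names(pt))
  if (length(miss_p))
    stop("patients file missing column(s): ", paste(miss_p, collapse = ", "),
         call. = FALSE)
  miss_s <- setdiff(required_sample_cols, names(sm))
  if (length(miss_s))
    stop("samples file missing column(s): ", paste(miss_s, collapse = ", "),
         call. = FALSE)
  for (col in c("tc_obs", "hdl_obs", "storage_time", "followup_time",
                "sample_date"))
    check_numeric_col(sm, col, basename(samples_path))
  for (col in c("age", "bmi", "inclusion_date"))
    check_numeric_col(pt, col, basename(patients_path))
  list(patients = pt, samples = sm)
}

#' Configure the end-to-end pipeline
#'
#' Collects every knob of the simulate/load → period test → confounder
#' screen → decay fit → correction → risk → reclassification pipeline.
#'
#' @param cohort_config a [cohort_config()] (used when simulating);
#'   ignored when `patients_csv`/`samples_csv` are given.
#' @param patients_csv,samples_csv optional input paths; when set the
#'   cohort is loaded instead of simulated.
#' @param out_dir output directory, or `NULL` to skip file output.
#' @param candidates candidate confounder terms for the >10% change rule.
#' @param threshold change-in-estimate threshold (default 0.10).
#' @param method estimation method for reported fits (default `"REML"`).
#' @param decay_override optional [decay_factor()] used instead of the
#'   fitted one (e.g. published decay rates).
#' @param variant,region SCORE variant and region calibration.
#' @param cutoffs risk-category cut points.
#' @param clamp_age clamp ages to SCORE's 20--85 range when scoring
#'   (default `TRUE`: cohorts legitimately include patients older than 85).
#' @param seed seed recorded in the manifest; overrides the cohort
#'   config's seed when simulating.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_config = lipidecay::cohort_config(),
                            patients_csv = NULL, samples_csv = NULL,
                            out_dir = NULL,
                            candidates = c("age", "sex", "bmi", "statin",
                                           "gluco", "das28", "rf_positive"),
                            threshold = 0.10,
                            method = "REML",
                            decay_override = NULL,
                            variant = c("tc_hdl_ratio", "total_cholesterol"),
                            region = c("low_risk", "high_risk"),
                            cutoffs = c(0.10, 0.20),
                            clamp_age = TRUE,
                            seed = NULL) {
  variant <- match.arg(variant)
  region <- match.arg(region)
  if (!is.null(decay_override)) stopifnot(inherits(decay_override, "decay_factor"))
  if (!is.null(patients_csv) &&
      (!file.exists(patients_csv) || !file.exists(samples_csv)))
    stop("input CSV path(s) not resolvable", call. = FALSE)
  if (is.null(seed)) seed <- cohort_config$seed
  cohort_config$seed <- as.integer(seed)
  structure(list(cohort_config = cohort_config, patients_csv = patients_csv,
                 samples_csv = samples_csv, out_dir = out_dir,
                 candidates = candidates, threshold = threshold,
                 method = method, decay_override = decay_override,
                 variant = variant, region = region, cutoffs = cutoffs,
                 clamp_age = clamp_age, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full storage-decay analysis pipeline
#'
#' Executes, in order: cohort simulation (or CSV load); the
#' period-effect test per lipid (confounders screened by the >10%
#' change-in-estimate rule on the subcohort-by-follow-up effects); the
#' storage-decay fit per lipid (confounders screened on the storage-time
#' effect); conversion of the fitted storage slopes into a decay
#' correction factor (unless overridden); correction of all samples;
#' SCORE 10-year risk per patient from the baseline sample, before and
#' after correction; and the reclassification summary. With `out_dir`
#' set, coefficient tables, the corrected samples, the risk table, the
#' reclassification summary and a run manifest (seed + configuration
#' hash) are written; every CSV carries the manifest line as a comment so
#' outputs of different runs cannot be mixed silently. Reruns with the
#' same configuration and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return list of class `pipeline_result`: `cohort`, `period_tests`,
#'   `confounders`, `fits`, `factor`, `samples_corrected`, `risk`,
#'   `reclass`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  hash <- config_hash(config)
  manifest <- c(sprintf("seed: %d", config$seed),
                sprintf("config_hash: %s", hash),
                sprintf("package: lipidecay %s",
                        as.character(utils::packageVersion("lipidecay"))))
  mline <- sprintf("run %s seed %d", hash, config$seed)

  cohort <- stage("cohort", {
    if (!is.null(config$patients_csv)) {
      say("loading cohort from CSV")
      read_cohort_csv(config$patients_csv, config$samples_csv)
    } else {
      say("simulating cohort (seed ", config$seed, ")")
      generate_cohort(config$cohort_config)
    }
  })
  pt <- cohort$patients; sm <- cohort$samples

  period_tests <- list(); confounders <- list(); fits <- list()
  for (resp in c("tc", "hdl")) {
    confounders[[resp]] <- stage(paste0("confounder_screen_", resp), {
      base <- lipid_design(resp, c("followup_time", "followup_time_sq",
                                   "subcohort", "subcohort:followup_time"))
      screen_confounders(pt, sm, base, config$candidates,
                         threshold = config$threshold,
                         method = config$method)
    })
    period_tests[[resp]] <- stage(paste0("period_effect_", resp),
      period_effect_test(pt, sm, resp, confounders = confounders[[resp]],
                         method = config$method))
    say(sprintf("period effect (%s): p = %.3g", resp,
                period_tests[[resp]]$p_value))
    fits[[resp]] <- stage(paste0("decay_fit_", resp), {
      base <- lipid_design(resp, c("storage_time", "followup_time",
                                   "followup_time_sq"))
      sel <- screen_confounders(pt, sm, base, config$candidates,
                                monitored = "^storage_time$",
                                threshold = config$threshold,
                                method = config$method)
      fit_random_intercept(pt, sm,
                           lipid_design(resp, c(base$terms, sel)),
                           method = config$method)
    })
  }

  fac <- stage("decay_factor", {
    if (!is.null(config$decay_override)) config$decay_override
    else decay_factor(factor_from_fit(fits$tc), factor_from_fit(fits$hdl),
                      source = sprintf("fitted (%s)", config$method))
  })
  say(sprintf("decay factor: TC %.4f, HDL %.4f mmol/L per year",
              fac$decay_tc, fac$decay_hdl))

  corrected <- stage("correction", correct_samples(sm, fac))

  risk <- stage("score_risk", {
    base_sm <- corrected[corrected$followup_time == min(corrected$followup_time), ]
    prof <- merge(pt[, c("patient_id", "age", "sex", "smoker")],
                  base_sm[, c("patient_id", "sbp", "tc_obs", "hdl_obs",
                              "tc_corrected", "hdl_corrected",
                              "ratio_observed", "ratio_corrected")],
                  by = "patient_id")
    prof <- prof[order(prof$patient_id), ]
    sc <- score_coefficients(region = config$region, variant = config$variant)
    chol_before <- if (config$variant == "tc_hdl_ratio") prof$ratio_observed
                   else prof$tc_obs
    chol_after <- if (config$variant == "tc_hdl_ratio") prof$ratio_corrected
                  else prof$tc_corrected
    pb <- data.frame(age = prof$age, sex = prof$sex, sbp = prof$sbp,
                     smoker = prof$smoker, chol = chol_before)
    pa <- pb; pa$chol <- chol_after
    rb <- ten_year_risk(pb, sc, cutoffs = config$cutoffs,
                        clamp_age = config$clamp_age)
    ra <- ten_year_risk(pa, sc, cutoffs = config$cutoffs,
                        clamp_age = config$clamp_age)
    data.frame(patient_id = prof$patient_id,
               risk_before = rb$risk_10yr, category_before = rb$category,
               risk_after = ra$risk_10yr, category_after = ra$category,
               stringsAsFactors = FALSE)
  })

  reclass <- stage("reclassification",
                   build_reclass_table(risk$category_before,
                                       risk$category_after))
  summ <- summarize_reclass(reclass)
  say(sprintf("%d of %d patients (%.0f%%) reclassified",
              summ$reclassified_n, summ$n_total, summ$reclassified_pct))

  result <- structure(list(cohort = cohort, period_tests = period_tests,
                           confounders = confounders, fits = fits,
                           factor = fac, samples_corrected = corrected,
                           risk = risk, reclass = reclass, summary = summ,
                           manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stage("write_outputs", {
      writeLines(manifest, file.path(dir, "manifest.txt"))
      write_cohort_csv(list(patients = pt, samples = corrected), dir,
                       header_lines = mline)
      for (resp in c("tc", "hdl")) {
        con <- file(file.path(dir, sprintf("coefficients_%s.csv", resp)), "w")
        writeLines(paste0("# ", mline), con)
        utils::write.csv(coef_table(fits[[resp]]), con, row.names = FALSE)
        close(con)
      }
      con <- file(file.path(dir, "risk.csv"), "w")
      writeLines(paste0("# ", mline), con)
      utils::write.csv(risk, con, row.names = FALSE)
      close(con)
      write_reclass_csv(summ, file.path(dir, "reclassification.csv"),
                        header_lines = mline)
    })
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Storage-decay pipeline result\n")
  cat(sprintf("  cohort: %d patients, %d samples\n",
              nrow(x$cohort$patients), nrow(x$cohort$samples)))
  for (resp in names(x$period_tests))
    cat(sprintf("  period effect (%s): p = %.3g\n", resp,
                x$period_tests[[resp]]$p_value))
  print(x$factor)
  print(x$summary)
  invisible(x)
}
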