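#' Wald chi-square test of fitted coefficients
#'
#' Joint Wald test that the named coefficients are all zero:
#' \eqn{W = \hat\beta' \hat V^{-1} \hat\beta} on as many degrees of freedom
#' as coefficients, compared to the chi-square upper tail. For a single
#' coefficient this reduces to \eqn{(\hat\beta/SE)^2}.
#'
#' @param fit a [fit_random_intercept()] result.
#' @param terms character vector of coefficient names (as in
#'   `names(coef(fit))`).
#' @return list of class `lipid_test`: `statistic`, `df`, `p_value`,
#'   `kind = "Wald"`, `terms`.
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "lipid_lmm"))
  if (!length(terms)) stop("empty term set", call. = FALSE)
  missing <- setdiff(terms, names(fit$coefficients))
  if (length(missing))
    stop("terms not in fit: ", paste(missing, collapse = ", "), call. = FALSE)
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  stat <- drop(crossprod(b, solve(V, b)))
  df <- length(terms)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 kind = "Wald", terms = terms),
            class = "lipid_test")
}

#' Likelihood-ratio test of nested lipid models
#'
#' \eqn{2(\ell_{full} - \ell_{reduced})} against the chi-square with
#' degrees of freedom equal to the difference in fixed-effect counts. Both
#' fits must be maximum-likelihood fits on the same observations: REML
#' likelihoods of models with different fixed effects are not comparable.
#'
#' @param fit_full,fit_reduced nested [fit_random_intercept()] ML fits.
#' @return list of class `lipid_test` (`kind = "LRT"`).
#' @export
lr_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "lipid_lmm"), inherits(fit_reduced, "lipid_lmm"))
  if (fit_full$method != "ML" || fit_reduced$method != "ML")
    stop("likelihood-ratio tests require ML fits; REML likelihoods of ",
         "models with different fixed effects are not comparable",
         call. = FALSE)
  if (fit_full$n_obs != fit_reduced$n_obs)
    stop("fits are not on identical observations", call. = FALSE)
  if (!all(fit_reduced$design$terms %in% fit_full$design$terms))
    stop("reduced model terms are not a subset of the full model",
         call. = FALSE)
  stat <- max(2 * (fit_full$logLik - fit_reduced$logLik), 0)
  df <- fit_full$n_fixed - fit_reduced$n_fixed
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 kind = "LRT",
                 terms = setdiff(fit_full$design$terms,
                                 fit_reduced$design$terms)),
            class = "lipid_test")
}

#' @export
print.lipid_test <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.4f, df = %d, p = %.4g\n",
              x$kind, x$statistic, x$df, x$p_value))
  invisible(x)
}

# subcohort-by-follow-up interaction coefficients, either term order
interaction_coef_regex <-
  "(^subcohort.+:followup_time$)|(^followup_time:subcohort.+$)"

#' Change-in-estimate confounder screen
#'
#' Adds each candidate covariate, one at a time, to the base model and
#' measures the relative change it induces in the monitored effect
#' estimates. Candidates whose maximal relative change
#' \eqn{|\beta_{new} - \beta_{base}| / |\beta_{base}|} exceeds the
#' threshold (default 10%) are flagged as confounders. If a monitored base
#' coefficient is exactly zero the change is measured on the absolute
#' scale divided by `zero_scale`.
#'
#' The monitored set defaults to the storage-time effect when present in
#' the design, otherwise to the subcohort-by-follow-up interaction
#' coefficients — the two effect sets the decay and period analyses watch.
#'
#' @param patients,samples cohort tables.
#' @param design the base [lipid_design()].
#' @param candidates character vector of candidate terms, disjoint from the
#'   design terms.
#' @param monitored regular expressions matched against coefficient names;
#'   `NULL` for the default described above.
#' @param threshold relative-change cut-off (default 0.10).
#' @param method estimation method for all fits (default `"REML"`).
#' @param zero_scale absolute-change scale used when a monitored base
#'   coefficient is exactly zero.
#' @return character vector of selected confounders, with a `details`
#'   attribute (data.frame of candidate and maximal relative change).
#' @export
screen_confounders <- function(patients, samples, design, candidates,
                               monitored = NULL, threshold = 0.10,
                               method = "REML", zero_scale = 1) {
  stopifnot(inherits(design, "lipid_design"))
  overlap <- intersect(candidates, design$terms)
  if (length(overlap))
    stop("candidates already in the design: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  base <- fit_random_intercept(patients, samples, design, method = method)
  if (is.null(monitored)) {
    monitored <- if ("storage_time" %in% design$terms) "^storage_time$"
                 else interaction_coef_regex
  }
  mon_names <- grep(paste(monitored, collapse = "|"),
                    names(base$coefficients), value = TRUE)
  if (!length(mon_names))
    stop("no monitored coefficients matched in the base model", call. = FALSE)
  b0 <- base$coefficients[mon_names]
  max_change <- vapply(candidates, function(cand) {
    d2 <- lipid_design(design$response, c(design$terms, cand), design$grouping)
    f2 <- fit_random_intercept(patients, samples, d2, method = method)
    b1 <- f2$coefficients[mon_names]
    denom <- abs(b0)
    change <- ifelse(denom == 0, abs(b1 - b0) / zero_scale,
                     abs(b1 - b0) / denom)
    max(change)
  }, numeric(1))
  selected <- candidates[max_change > threshold]
  attr(selected, "details") <- data.frame(candidate = candidates,
                                          max_rel_change = unname(max_change),
                                          selected = max_change > threshold,
                                          stringsAsFactors = FALSE)
  selected
}

#' Test for a period effect in the lipid course
#'
#' Fits the confounder-adjusted random-intercept model with follow-up time,
#' its square, subcohort indicators and subcohort-by-follow-up
#' interactions, and returns the joint Wald test of all interaction
#' coefficients — the test of whether the course of the lipid over
#' follow-up differs between inclusion-period subcohorts.
#'
#' @param patients,samples cohort tables.
#' @param response `"tc"`, `"hdl"` or `"ldl"`.
#' @param confounders additional adjustment terms (e.g. `c("age", "sex",
#'   "bmi")`).
#' @param method estimation method (default `"REML"`).
#' @return list of class `lipid_test` with the fitted model attached as
#'   attribute `fit`.
#' @export
period_effect_test <- function(patients, samples, response,
                               confounders = character(), method = "REML") {
  dat <- merge(samples, patients[, c("patient_id", "subcohort")],
               by = "patient_id")
  n_ft <- tapply(dat$followup_time, dat$subcohort,
                 function(x) length(unique(x)))
  if (length(n_ft) < 2)
    stop("period-effect test needs at least 2 subcohorts", call. = FALSE)
  if (any(n_ft < 2))
    stop("subcohort(s) with a single follow-up time: ",
         paste(names(n_ft)[n_ft < 2], collapse = ", "), call. = FALSE)
  des <- lipid_design(response,
                      c("followup_time", "followup_time_sq", "subcohort",
                        "subcohort:followup_time", confounders))
  fit <- fit_random_intercept(patients, samples, des, method = method)
  inter <- grep(interaction_coef_regex, names(fit$coefficients), value = TRUE)
  out <- wald_test(fit, inter)
  attr(out, "fit") <- fit
  out
}
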