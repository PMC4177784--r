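#' Specify a longitudinal lipid model design
#'
#' Describes the fixed-effect structure of a random-intercept lipid model:
#' which lipid is the response and which terms enter the mean model. The
#' intercept is always included. `followup_time_sq` (the quadratic
#' follow-up term) requires `followup_time`; the `subcohort:followup_time`
#' interaction requires both main effects.
#'
#' Recognised term names: `storage_time`, `followup_time`,
#' `followup_time_sq`, `subcohort` (indicator-coded, first period as
#' reference), `subcohort:followup_time`, and the covariates `age`, `sex`,
#' `bmi`, `smoker`, `statin`, `gluco`, `das28`, `rf_positive`, `sbp`.
#'
#' @param response one of `"tc"`, `"hdl"`, `"ldl"`. LDL is computed by the
#'   Friedewald formula from observed TC, HDL and TG; samples where the
#'   formula is invalid (TG > 4.5 mmol/L or a non-positive result) are
#'   dropped with a message.
#' @param terms character vector of fixed-effect terms (excluding the
#'   intercept).
#' @param grouping name of the patient identifier column.
#' @return An object of class `lipid_design`.
#' @examples
#' lipid_design("tc", c("storage_time", "followup_time", "followup_time_sq",
#'                      "age", "sex"))
#' @export
lipid_design <- function(response = c("tc", "hdl", "ldl"),
                         terms,
                         grouping = "patient_id") {
  response <- match.arg(response)
  if (missing(terms)) terms <- character()
  stopifnot(is.character(terms))
  if (anyDuplicated(terms))
    stop("duplicated design terms: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "), call. = FALSE)
  if ("followup_time_sq" %in% terms && !"followup_time" %in% terms)
    stop("'followup_time_sq' requires 'followup_time' in the design",
         call. = FALSE)
  if ("subcohort:followup_time" %in% terms &&
      !all(c("subcohort", "followup_time") %in% terms))
    stop("'subcohort:followup_time' requires both main effects in the design",
         call. = FALSE)
  structure(list(response = response, terms = terms, grouping = grouping),
            class = "lipid_design")
}

# response column + merged model data for a design
build_model_data <- function(patients, samples, design) {
  dat <- merge(samples, patients, by = design$grouping, sort = FALSE,
               suffixes = c("", ".pt"))
  dat$followup_time_sq <- dat$followup_time^2
  if ("subcohort" %in% names(dat)) dat$subcohort <- factor(dat$subcohort)
  if ("sex" %in% names(dat)) dat$sex <- factor(dat$sex, levels = c("male", "female"))
  y <- switch(design$response,
    tc = dat$tc_obs,
    hdl = dat$hdl_obs,
    ldl = {
      ldl <- suppressWarnings(friedewald_ldl(dat$tc_obs, dat$hdl_obs,
                                             dat$tg_obs, strict = FALSE))
      ldl
    })
  keep <- !is.na(y)
  if (!all(keep)) {
    message(sum(!keep), " samples dropped (invalid ", design$response,
            " response)")
    dat <- dat[keep, , drop = FALSE]
    y <- y[keep]
  }
  dat$.response <- y
  dat
}

design_formula <- function(design) {
  if (!length(design$terms)) return(stats::as.formula(".response ~ 1"))
  stats::reformulate(design$terms, response = ".response")
}

# -2 profiled log-likelihood machinery for y = X beta + b_g + e,
# b ~ N(0, lambda * sigma_e^2), via closed-form compound-symmetry inversion:
# V_g^{-1} = (I - s_g J) / sigma_e^2 with s_g = lambda / (1 + n_g * lambda).
profile_objective <- function(lam, pre, reml) {
  s <- lam / (1 + pre$ni * lam)
  A <- pre$XtX - crossprod(pre$U * sqrt(s))
  bvec <- pre$Xty - crossprod(pre$U, s * pre$V)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(val = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), bvec))
  yWy <- pre$yty - sum(s * pre$V^2)
  rss <- yWy - sum(bvec * beta)
  if (rss <= 0) rss <- .Machine$double.eps
  n <- pre$n; p <- pre$p
  if (reml) {
    sig2 <- rss / (n - p)
    val <- (n - p) * log(2 * pi * sig2) + sum(log1p(pre$ni * lam)) +
      2 * sum(log(diag(ch))) + (n - p)
  } else {
    sig2 <- rss / n
    val <- n * log(2 * pi * sig2) + sum(log1p(pre$ni * lam)) + n
  }
  list(val = val, beta = beta, sig2 = sig2, A = A)
}

# analytic gradient of the -2 profiled log-likelihood w.r.t. lambda
# (envelope theorem for the profiled beta and sigma_e^2)
profile_gradient <- function(lam, pre, reml) {
  s <- lam / (1 + pre$ni * lam)
  ds <- 1 / (1 + pre$ni * lam)^2
  A <- pre$XtX - crossprod(pre$U * sqrt(s))
  bvec <- pre$Xty - crossprod(pre$U, s * pre$V)
  ch <- chol(A)
  beta <- backsolve(ch, forwardsolve(t(ch), bvec))
  yWy <- pre$yty - sum(s * pre$V^2)
  rss <- yWy - sum(bvec * beta)
  rsum <- pre$V - drop(pre$U %*% beta)
  drss <- -sum(ds * rsum^2)
  dfree <- if (reml) pre$n - pre$p else pre$n
  g <- sum(pre$ni / (1 + pre$ni * lam)) + dfree * drss / rss
  if (reml) {
    AinvUt <- backsolve(ch, forwardsolve(t(ch), t(pre$U)))
    quad <- colSums(t(pre$U) * AinvUt)
    g <- g - sum(ds * quad)
  }
  g
}

#' Fit a random-intercept longitudinal lipid model
#'
#' Fits \eqn{y_{ij} = x_{ij}'\beta + b_i + \varepsilon_{ij}} with
#' patient-level random intercepts \eqn{b_i \sim N(0, \sigma_b^2)} and
#' residuals \eqn{\varepsilon_{ij} \sim N(0, \sigma_e^2)} by maximising the
#' Gaussian (restricted) log-likelihood. The likelihood is profiled over
#' \eqn{\lambda = \sigma_b^2/\sigma_e^2} using the closed-form
#' compound-symmetry inverse, and maximised with a bounded scalar
#' optimiser on \eqn{\log\lambda} (tolerance 1e-12 after refinement, with
#' an explicit check of the \eqn{\sigma_b^2 = 0} boundary). Fixed-effect
#' covariances are model-based, \eqn{\hat\sigma_e^2 (X'\hat W X)^{-1}}.
#'
#' @param patients,samples cohort tables as produced by
#'   [generate_cohort()] or [read_cohort_csv()].
#' @param design a [lipid_design()].
#' @param method `"REML"` (default, for reported coefficients) or `"ML"`
#'   (required for likelihood-ratio tests).
#' @return An object of class `lipid_lmm` with elements `coefficients`,
#'   `se`, `vcov`, `sigma2_b`, `sigma2_e`, `logLik`, `n_obs`,
#'   `n_patients`, `method`, `design`.
#' @seealso [coef_table()], [wald_test()], [lr_test()],
#'   [screen_confounders()], [period_effect_test()]
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients_per_subcohort = 10, seed = 3))
#' des <- lipid_design("tc", c("storage_time", "followup_time",
#'                             "followup_time_sq", "age", "sex"))
#' fit <- fit_random_intercept(coh$patients, coh$samples, des)
#' coef_table(fit)
#' @export
fit_random_intercept <- function(patients, samples, design,
                                 method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "lipid_design"))
  dat <- build_model_data(patients, samples, design)
  if (length(unique(dat[[design$grouping]])) < 2)
    stop("need at least 2 patients to fit a random-intercept model",
         call. = FALSE)
  X <- stats::model.matrix(design_formula(design), dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  y <- dat$.response
  g <- factor(dat[[design$grouping]])

  pre <- list(
    XtX = crossprod(X),
    Xty = drop(crossprod(X, y)),
    yty = sum(y^2),
    U = rowsum(X, g),
    V = drop(rowsum(y, g)),
    ni = as.vector(table(g)),
    n = nrow(X), p = ncol(X)
  )
  reml <- method == "REML"
  f <- function(ll) profile_objective(exp(ll), pre, reml)$val
  opt <- stats::optimize(f, interval = c(-20, 20), tol = 1e-8)
  # refine locally, then polish with the analytic gradient (scalar
  # optimisation alone leaves ~1e-7 slack in the variance components)
  opt2 <- stats::optimize(f, interval = opt$minimum + c(-0.5, 0.5), tol = 1e-12)
  lam_hat <- exp(opt2$minimum)
  gr <- function(ll) profile_gradient(exp(ll), pre, reml)
  lo <- opt2$minimum - 0.3
  hi <- opt2$minimum + 0.3
  glo <- tryCatch(gr(lo), error = function(e) NA_real_)
  ghi <- tryCatch(gr(hi), error = function(e) NA_real_)
  if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0) {
    root <- tryCatch(stats::uniroot(gr, c(lo, hi), tol = 1e-13),
                     error = function(e) NULL)
    if (!is.null(root)) lam_hat <- exp(root$root)
  }
  best <- profile_objective(lam_hat, pre, reml)
  at_zero <- profile_objective(0, pre, reml)
  if (at_zero$val <= best$val) {
    lam_hat <- 0
    best <- at_zero
  }
  vc <- best$sig2 * chol2inv(chol(best$A))
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- drop(best$beta)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    sigma2_b = lam_hat * best$sig2,
    sigma2_e = best$sig2,
    logLik = -best$val / 2,
    n_obs = pre$n,
    n_patients = length(pre$ni),
    n_fixed = pre$p,
    method = method,
    design = design
  ), class = "lipid_lmm")
}

#' Coefficient table of a fitted lipid model
#'
#' Estimates, model-based standard errors, Wald 95% confidence intervals
#' (estimate ± 1.96 SE) and two-sided normal p-values, in the column order
#' of a standard longitudinal regression report.
#'
#' @param fit a [fit_random_intercept()] result.
#' @param ci_level confidence level (default 0.95).
#' @return data.frame with columns `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
coef_table <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "lipid_lmm"))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- fit$coefficients
  se <- fit$se
  data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_lower = unname(est - z * se),
    ci_upper = unname(est + z * se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.lipid_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept lipid model (%s), response '%s'\n",
              x$method, x$design$response))
  cat(sprintf("  %d observations, %d patients; logLik %.3f\n",
              x$n_obs, x$n_patients, x$logLik))
  cat(sprintf("  sigma_b^2 = %.5f, sigma_e^2 = %.5f\n", x$sigma2_b, x$sigma2_e))
  print(format(coef_table(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
logLik.lipid_lmm <- function(object, ...) {
  structure(object$logLik,
            df = object$n_fixed + 2,
            nobs = object$n_obs, class = "logLik")
}

#' @export
coef.lipid_lmm <- function(object, ...) object$coefficients

#' @export
vcov.lipid_lmm <- function(object, ...) object$vcov
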