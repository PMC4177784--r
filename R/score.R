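#' Load SCORE model coefficients
#'
#' Reads the versioned constants file shipped with the package (Weibull
#' baseline parameters per region, sex and cause, and centred risk-factor
#' coefficients per cause) and returns the subset for one region and
#' cholesterol variant. SCORE models fatal cardiovascular risk as the sum
#' of a coronary (CHD) and a non-coronary (non-CHD) cause, each with a
#' Weibull baseline survival \eqn{S_0(age) = \exp(-e^{\alpha}(age-20)^p)}
#' and a proportional-hazards factor \eqn{e^w},
#' \eqn{w = \sum_k \beta_k (x_k - ref_k)}.
#'
#' @param region `"low_risk"` (default; e.g. the Netherlands) or
#'   `"high_risk"`.
#' @param variant cholesterol term: `"tc_hdl_ratio"` (default) or
#'   `"total_cholesterol"`.
#' @param path optional path to an alternative constants file in the same
#'   CSV dialect.
#' @return object of class `score_coefficients`: nested list
#'   `baseline[[cause]][[sex]] = c(alpha, p)`, `betas[[cause]]` /
#'   `refs[[cause]]` named by factor (`cholesterol`, `sbp`, `smoker`),
#'   plus `region` and `variant`.
#' @examples
#' sc <- score_coefficients()
#' sc$baseline$chd$male
#' @export
score_coefficients <- function(region = c("low_risk", "high_risk"),
                               variant = c("tc_hdl_ratio", "total_cholesterol"),
                               path = NULL) {
  region <- match.arg(region)
  variant <- match.arg(variant)
  if (is.null(path))
    path <- system.file("extdata", "score_coefficients_conroy2003.csv",
                        package = "lipidecay", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  causes <- c("chd", "nonchd")
  sexes <- c("male", "female")
  factors <- c("cholesterol", "sbp", "smoker")
  baseline <- lapply(causes, function(cs) {
    out <- lapply(sexes, function(sx) {
      rows <- tab[tab$type == "baseline" & tab$region == region &
                    tab$cause == cs & tab$sex == sx, ]
      a <- rows$value[rows$parameter == "alpha"]
      p <- rows$value[rows$parameter == "p"]
      if (length(a) != 1 || length(p) != 1)
        stop(sprintf("missing baseline coefficient: region %s, cause %s, sex %s",
                     region, cs, sx), call. = FALSE)
      if (p <= 0)
        stop(sprintf("Weibull shape p must be positive (cause %s, sex %s)",
                     cs, sx), call. = FALSE)
      c(alpha = a, p = p)
    })
    names(out) <- sexes
    out
  })
  names(baseline) <- causes
  betas <- refs <- list()
  for (cs in causes) {
    rows <- tab[tab$type == "beta" & tab$variant == variant & tab$cause == cs, ]
    miss <- setdiff(factors, rows$parameter)
    if (length(miss))
      stop(sprintf("missing beta coefficient(s) for cause %s, variant %s: %s",
                   cs, variant, paste(miss, collapse = ", ")), call. = FALSE)
    betas[[cs]] <- stats::setNames(rows$value, rows$parameter)[factors]
    refs[[cs]] <- stats::setNames(rows$reference, rows$parameter)[factors]
  }
  structure(list(baseline = baseline, betas = betas, refs = refs,
                 region = region, variant = variant, file = path),
            class = "score_coefficients")
}

#' @export
print.score_coefficients <- function(x, ...) {
  cat(sprintf("SCORE coefficients: region %s, variant %s\n", x$region, x$variant))
  cat(sprintf("  file: %s\n", basename(x$file)))
  invisible(x)
}

#' SCORE Weibull baseline survival
#'
#' \eqn{S_0(age) = \exp(-e^{\alpha}(age - 20)^p)}: the probability of
#' surviving the cause from age 20 to `age` at reference risk-factor
#' levels. Ages at or below 20 give exactly 1.
#'
#' @param age age in years (vectorized).
#' @param alpha Weibull location (log scale).
#' @param p Weibull shape (> 0).
#' @return survival probability in (0, 1].
#' @examples
#' baseline_survival(65, -22.1, 4.71)
#' @export
baseline_survival <- function(age, alpha, p) {
  if (p <= 0) stop("Weibull shape p must be positive", call. = FALSE)
  exp(-exp(alpha) * pmax(age - 20, 0)^p)
}

# 10-year risk for one cause, vectorized over profiles
cause_risk <- function(age, sex, w, baseline) {
  s_now <- s_then <- numeric(length(age))
  for (sx in c("male", "female")) {
    i <- sex == sx
    if (!any(i)) next
    ap <- baseline[[sx]]
    s_now[i] <- baseline_survival(age[i], ap["alpha"], ap["p"])
    s_then[i] <- baseline_survival(age[i] + 10, ap["alpha"], ap["p"])
  }
  ew <- exp(w)
  1 - (s_then^ew) / (s_now^ew)
}

#' SCORE 10-year fatal cardiovascular risk
#'
#' Computes, per profile, the 10-year risk of a fatal cardiovascular event
#' as the sum of the CHD and non-CHD cause risks. For each cause the
#' centred linear predictor \eqn{w = \sum_k \beta_k (x_k - ref_k)} scales
#' the Weibull baseline survival, and the 10-year conditional risk is
#' \eqn{1 - S_0(age+10)^{e^w} / S_0(age)^{e^w}}.
#'
#' @param profiles data.frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `sbp` (mmHg), `smoker` (logical) and `chol`
#'   (the cholesterol term of the loaded variant: TC in mmol/L, or the
#'   TC:HDL ratio).
#' @param coeffs a [score_coefficients()] object.
#' @param cutoffs risk-category cut points passed to [classify_risk()].
#' @param clamp_age SCORE is calibrated for ages 20--85; by default ages
#'   outside 19--85 are an error. `clamp_age = TRUE` clamps to that range
#'   instead (an explicit choice when scoring e.g. elderly cohort members).
#' @return `profiles` with columns `risk_10yr` (fraction in \[0, 1\]) and
#'   `category` (factor low/intermediate/high) appended.
#' @examples
#' sc <- score_coefficients(variant = "total_cholesterol")
#' p <- data.frame(age = 60, sex = "male", sbp = 140, smoker = FALSE, chol = 5)
#' ten_year_risk(p, sc)
#' @export
ten_year_risk <- function(profiles, coeffs, cutoffs = c(0.10, 0.20),
                          clamp_age = FALSE) {
  stopifnot(inherits(coeffs, "score_coefficients"))
  need <- c("age", "sex", "sbp", "smoker", "chol")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop("profiles lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  age <- profiles$age
  if (clamp_age) {
    age <- pmin(pmax(age, 20), 85)
  } else if (any(age < 19 | age > 85)) {
    stop("age outside the calibrated range 19-85; ",
         "use clamp_age = TRUE to clamp explicitly", call. = FALSE)
  }
  if (any(profiles$sbp < 70 | profiles$sbp > 260))
    stop("sbp outside plausible range 70-260 mmHg", call. = FALSE)
  if (any(profiles$chol <= 0))
    stop("cholesterol term must be positive", call. = FALSE)
  if (!all(profiles$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  smoker <- as.numeric(profiles$smoker)
  total <- 0
  for (cs in c("chd", "nonchd")) {
    b <- coeffs$betas[[cs]]
    r <- coeffs$refs[[cs]]
    w <- b["cholesterol"] * (profiles$chol - r["cholesterol"]) +
      b["sbp"] * (profiles$sbp - r["sbp"]) +
      b["smoker"] * (smoker - r["smoker"])
    total <- total + cause_risk(age, profiles$sex, w, coeffs$baseline[[cs]])
  }
  profiles$risk_10yr <- pmin(unname(total), 1)
  profiles$category <- classify_risk(profiles$risk_10yr, cutoffs)
  profiles
}

#' Categorize a 10-year cardiovascular risk
#'
#' Three categories: low (risk below the first cut-off), intermediate
#' (between the cut-offs, both ends inclusive) and high (above the second
#' cut-off). Defaults are the clinical 10% and 20% thresholds.
#'
#' @param risk_10yr risk fraction(s) in \[0, 1\].
#' @param cutoffs numeric pair `c(low_upper, intermediate_upper)`.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @examples
#' classify_risk(c(0.099, 0.10, 0.20, 0.201))
#' @export
classify_risk <- function(risk_10yr, cutoffs = c(0.10, 0.20)) {
  if (any(is.na(risk_10yr)) || any(risk_10yr < 0 | risk_10yr > 1))
    stop("risk must be in [0, 1]", call. = FALSE)
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  out <- ifelse(risk_10yr < cutoffs[1], "low",
                ifelse(risk_10yr <= cutoffs[2], "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"))
}
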