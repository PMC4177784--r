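#' Lipid storage-decay correction factors
#'
#' A decay factor is the estimated loss of measured cholesterol per year of
#' frozen storage, in mmol/L per storage-year. Applied additively,
#' corrected = observed + decay x storage years, it back-projects a
#' measurement to the level at the time the sample was drawn.
#'
#' @param decay_tc,decay_hdl per-year decay for total and HDL cholesterol
#'   (mmol/L per storage-year; a positive value means loss during storage).
#' @param source free-text provenance (fit identifier or description).
#' @return object of class `decay_factor`.
#' @examples
#' decay_factor(0.030, 0.024)
#' @export
decay_factor <- function(decay_tc, decay_hdl, source = "user-specified") {
  decay_tc <- as.vector(decay_tc)
  decay_hdl <- as.vector(decay_hdl)
  if (!is_number(decay_tc) || !is_number(decay_hdl))
    stop("decay rates must be finite numbers", call. = FALSE)
  if (decay_tc < 0 || decay_hdl < 0)
    warning("negative decay rate: storage 'gain' will be subtracted",
            call. = FALSE)
  structure(list(decay_tc = decay_tc, decay_hdl = decay_hdl, source = source),
            class = "decay_factor")
}

#' @export
print.decay_factor <- function(x, ...) {
  cat(sprintf(
    "Lipid storage decay factor (%s):\n  TC %.4f, HDL-c %.4f mmol/L per storage-year\n",
    x$source, x$decay_tc, x$decay_hdl))
  invisible(x)
}

#' Extract a decay rate from a fitted model
#'
#' The decay rate is minus the fitted storage-time coefficient: a negative
#' slope of lipid level on storage years becomes a positive per-year loss
#' that the correction adds back.
#'
#' @param fit a [fit_random_intercept()] result whose design contains
#'   `storage_time`.
#' @return the decay rate (mmol/L per storage-year), with the fit's
#'   standard error as attribute `se`.
#' @examples
#' \dontrun{decay <- factor_from_fit(fit_tc)}
#' @export
factor_from_fit <- function(fit) {
  stopifnot(inherits(fit, "lipid_lmm"))
  if (!"storage_time" %in% names(fit$coefficients))
    stop("fit has no 'storage_time' term", call. = FALSE)
  structure(-unname(fit$coefficients["storage_time"]),
            se = unname(fit$se["storage_time"]))
}

#' Correct an observed lipid level for storage decay
#'
#' corrected = observed + decay x storage. Exact arithmetic, vectorized;
#' the inverse is observed = corrected − decay x storage.
#'
#' @param observed measured lipid level, mmol/L (> 0).
#' @param decay decay rate, mmol/L per storage-year.
#' @param storage storage time in years (>= 0).
#' @return corrected lipid level, mmol/L.
#' @examples
#' correct_lipid(4.20, 0.030, 26)  # 4.98
#' @export
correct_lipid <- function(observed, decay, storage) {
  if (any(storage < 0)) stop("negative storage time", call. = FALSE)
  if (any(observed <= 0)) stop("observed lipid must be positive", call. = FALSE)
  observed + decay * storage
}

#' Friedewald LDL cholesterol
#'
#' LDL = TC − HDL − TG/2.2 in mmol/L units. The formula is invalid for
#' TG > 4.5 mmol/L (about 400 mg/dL); with `strict = TRUE` (default) such
#' input is an error, with `strict = FALSE` it yields `NA`. A non-positive
#' result is never returned as a lipid value: it is `NA` with a warning.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol and triglycerides,
#'   mmol/L (vectorized).
#' @param strict error (rather than `NA`) on TG > 4.5 mmol/L?
#' @return LDL cholesterol, mmol/L.
#' @examples
#' friedewald_ldl(5.2, 1.2, 2.2)  # 3.0
#' @export
friedewald_ldl <- function(tc, hdl, tg, strict = TRUE) {
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n); tg <- rep_len(tg, n)
  bad_tg <- !is.na(tg) & tg > 4.5
  if (any(bad_tg)) {
    if (strict)
      stop("Friedewald formula invalid for TG > 4.5 mmol/L", call. = FALSE)
    tg[bad_tg] <- NA_real_
  }
  ldl <- tc - hdl - tg / 2.2
  neg <- !is.na(ldl) & ldl <= 0
  if (any(neg)) {
    warning(sum(neg), " non-positive LDL value(s) flagged invalid (NA)",
            call. = FALSE)
    ldl[neg] <- NA_real_
  }
  ldl
}

#' Total-to-HDL cholesterol ratio
#'
#' @param tc,hdl cholesterol levels, mmol/L (HDL must be positive).
#' @return dimensionless ratio TC/HDL.
#' @examples
#' tc_hdl_ratio(4.5, 0.9)  # 5
#' @export
tc_hdl_ratio <- function(tc, hdl) {
  if (any(hdl <= 0)) stop("HDL must be positive", call. = FALSE)
  tc / hdl
}

#' Apply the storage-decay correction to a sample table
#'
#' Adds `tc_corrected`, `hdl_corrected`, `ratio_observed` and
#' `ratio_corrected` columns. LDL, when present or requested, is *not*
#' corrected directly (no storage effect on LDL is assumed); instead
#' `ldl_corrected` is recomputed by the Friedewald formula from corrected
#' TC and HDL with the observed TG.
#'
#' @param samples sample table with `tc_obs`, `hdl_obs`, `storage_time`
#'   (and `tg_obs` if `add_ldl`).
#' @param factor a [decay_factor()].
#' @param add_ldl also add `ldl_observed` / `ldl_corrected` Friedewald
#'   columns (invalid values become `NA`)?
#' @return the sample table with the correction columns appended.
#' @export
correct_samples <- function(samples, factor, add_ldl = FALSE) {
  stopifnot(inherits(factor, "decay_factor"))
  need <- c("tc_obs", "hdl_obs", "storage_time")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("samples table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  samples$tc_corrected <- correct_lipid(samples$tc_obs, factor$decay_tc,
                                        samples$storage_time)
  samples$hdl_corrected <- correct_lipid(samples$hdl_obs, factor$decay_hdl,
                                         samples$storage_time)
  samples$ratio_observed <- tc_hdl_ratio(samples$tc_obs, samples$hdl_obs)
  samples$ratio_corrected <- tc_hdl_ratio(samples$tc_corrected,
                                          samples$hdl_corrected)
  if (add_ldl) {
    if (!"tg_obs" %in% names(samples))
      stop("samples table lacks column(s): tg_obs", call. = FALSE)
    samples$ldl_observed <- suppressWarnings(
      friedewald_ldl(samples$tc_obs, samples$hdl_obs, samples$tg_obs,
                     strict = FALSE))
    samples$ldl_corrected <- suppressWarnings(
      friedewald_ldl(samples$tc_corrected, samples$hdl_corrected,
                     samples$tg_obs, strict = FALSE))
  }
  samples
}
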