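# independent scalar re-implementation of the SCORE risk algorithm, used
# as the oracle against the vectorized engine; parses the constants file
# on its own

oracle_score_constants <- function() {
  path <- system.file("extdata", "score_coefficients_conroy2003.csv",
                      package = "lipidecay", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1]]
  rows <- lapply(fields[-1], function(f) {
    f <- c(f, rep("", length(header) - length(f)))
    stats::setNames(as.list(f), header)
  })
  rows
}

oracle_score_risk <- function(age, sex, sbp, smoker, chol,
                              region = "low_risk", variant = "tc_hdl_ratio") {
  rows <- oracle_score_constants()
  getv <- function(type, cause, want, sexq = "", variantq = "") {
    for (r in rows) {
      if (r$type == type && r$cause == cause && r$parameter == want &&
          (type != "baseline" || (r$region == region && r$sex == sexq)) &&
          (type != "beta" || r$variant == variantq))
        return(r)
    }
    stop("oracle: constant not found")
  }
  total <- 0
  for (cause in c("chd", "nonchd")) {
    alpha <- as.numeric(getv("baseline", cause, "alpha", sexq = sex)$value)
    p <- as.numeric(getv("baseline", cause, "p", sexq = sex)$value)
    w <- 0
    for (fac in c("cholesterol", "sbp", "smoker")) {
      r <- getv("beta", cause, fac, variantq = variant)
      x <- switch(fac, cholesterol = chol, sbp = sbp,
                  smoker = as.numeric(smoker))
      w <- w + as.numeric(r$value) * (x - as.numeric(r$reference))
    }
    s0 <- function(a) exp(-exp(alpha) * max(a - 20, 0)^p)
    s_now <- s0(age)^exp(w)
    s_then <- s0(age + 10)^exp(w)
    total <- total + (1 - s_then / s_now)
  }
  min(total, 1)
}
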