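## small shared helpers (internal)

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# truncated-normal draw by resampling; floor/ceiling are hard bounds
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf, max_tries = 100L) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
  }
  pmin(pmax(x, lower), upper)
}
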