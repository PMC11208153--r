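# Internal numeric helpers shared across modules.

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# truncate toward zero at a number of decimal digits
trunc_digits <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
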