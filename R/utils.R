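# internal helpers shared across modules

# trapezoidal integral of y(t); t in ms, y in pA -> pA.ms
trapz_ms <- function(t, y) pracma::trapz(t, y)

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  invisible(x)
}

# linear interpolation restricted to [t[1], t[n]]
interp_lin <- function(t, y, tout) {
  stats::approx(t, y, xout = tout, method = "linear", rule = 2)$y
}
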