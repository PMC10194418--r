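#' Repolarization power: time integral of the AP-clamp current
#'
#' The repolarization power is the trapezoidal time integral of the recorded
#' current over an integration window, expressed in pA.s (or pA/pF.s for
#' density-normalized traces). Negative excursions (e.g. the late inward
#' contamination artifact) integrate with their sign; the recorded current is
#' integrated as-is. The default window is the full trace span: current
#' during the holding segments is essentially zero for clean traces, so this
#' choice is inert, and the window actually used is reported in the result so
#' it can be restricted to the AP proper when leak matters.
#'
#' @param trace a [current_trace()].
#' @param window_start,window_end integration window, ms, within the trace
#'   span; default full span. Endpoints falling between samples are handled
#'   by linear interpolation.
#' @return An object of class `repower_result` with fields `value` (pA.s),
#'   `window_start`, `window_end`, `trace_id`, `density_normalized`.
#' @export
repolarization_power <- function(trace, window_start = NULL,
                                 window_end = NULL) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  t <- trace$times
  if (is.null(window_start)) window_start <- t[1L]
  if (is.null(window_end)) window_end <- t[length(t)]
  check_scalar(window_start, "window_start")
  check_scalar(window_end, "window_end")
  if (window_end <= window_start)
    stop_field("window_end", "must exceed window_start")
  if (window_start < t[1L] || window_end > t[length(t)])
    stop("integration window lies outside the trace time span", call. = FALSE)
  inside <- t > window_start & t < window_end
  tt <- c(window_start, t[inside], window_end)
  yy <- c(interp_lin(t, trace$current, window_start),
          trace$current[inside],
          interp_lin(t, trace$current, window_end))
  structure(
    list(value = trapz_ms(tt, yy) / 1000,
         window_start = window_start, window_end = window_end,
         trace_id = trace$cell_id,
         density_normalized = trace$density_normalized),
    class = "repower_result")
}

#' @export
print.repower_result <- function(x, ...) {
  cat(sprintf("<repower_result> %.4g %s over [%.1f, %.1f] ms%s\n",
              x$value, if (x$density_normalized) "pA/pF.s" else "pA.s",
              x$window_start, x$window_end,
              if (nzchar(x$trace_id)) paste0(" (", x$trace_id, ")") else ""))
  invisible(x)
}

#' Correct a recording made under a time-dilated protocol
#'
#' Undoes the protocol dilation on the recorded trace: time is divided by the
#' dilation factor and the current multiplied by the same factor, so that a
#' recording obtained under a slowed AP is mapped back onto the standard time
#' base while preserving its time integral exactly. The corrected trace has
#' `dilation_factor == 1`.
#'
#' @param trace a [current_trace()].
#' @param factor positive dilation factor used for the recording; a warning
#'   is issued if it disagrees with the trace's own `dilation_factor`.
#' @return The corrected [current_trace()].
#' @export
correct_trace <- function(trace, factor) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  check_scalar(factor, "factor", positive = TRUE)
  if (!isTRUE(all.equal(trace$dilation_factor, factor)))
    warning(sprintf(
      "correcting with factor %g but trace records dilation_factor %g",
      factor, trace$dilation_factor))
  out <- trace
  out$times <- trace$times / factor
  out$current <- trace$current * factor
  out$dilation_factor <- 1
  out$meta$corrected_with_factor <- factor
  out
}

#' Time at which the current is maximal
#'
#' The secondary indicator complementing the repolarization power: the time
#' of the maximum current sample. A variant can reach a wild-type-like
#' integral with altered kinetics; the peak time exposes that. Ties are
#' broken towards the earliest time. An all-equal (degenerate) trace returns
#' the window start with a warning.
#'
#' @param trace a [current_trace()].
#' @return Peak time, ms (scalar).
#' @export
time_of_peak <- function(trace) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  cur <- trace$current
  if (diff(range(cur)) == 0) {
    warning("degenerate trace: all samples equal; returning window start")
    return(trace$times[1L])
  }
  trace$times[which.max(cur)]
}

#' Normalize a trace to its peak current
#'
#' Divides the current by its maximum so profiles of different amplitude can
#' be compared on shape alone (e.g. corrected room-temperature variant
#' profiles against the wild type).
#'
#' @param trace a [current_trace()] with positive maximum current.
#' @return The normalized [current_trace()]; `meta$normalized_to_peak` is set.
#' @export
normalize_to_peak <- function(trace) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  m <- max(trace$current)
  if (m <= 0)
    stop("cannot normalize: maximum current is not positive", call. = FALSE)
  out <- trace
  out$current <- trace$current / m
  out$meta$normalized_to_peak <- TRUE
  out
}

#' RMS discrepancy between two traces
#'
#' Linearly resamples both traces onto a common uniform grid spanning the
#' overlap of their time ranges, at the finer of the two native sampling
#' intervals, and returns the root-mean-square difference. Quantifies how
#' well a corrected room-temperature trace overlaps the reference.
#'
#' @param a,b [current_trace()] objects with overlapping time spans.
#' @return RMS difference (pA, or pA/pF for density-normalized traces).
#' @export
trace_discrepancy <- function(a, b) {
  if (!inherits(a, "current_trace") || !inherits(b, "current_trace"))
    stop("both arguments must be current_trace objects", call. = FALSE)
  lo <- max(a$times[1L], b$times[1L])
  hi <- min(a$times[length(a$times)], b$times[length(b$times)])
  if (hi <= lo) stop("traces have no overlapping time span", call. = FALSE)
  dt <- min(min(diff(a$times)), min(diff(b$times)))
  grid <- seq(lo, hi, by = dt)
  da <- interp_lin(a$times, a$current, grid)
  db <- interp_lin(b$times, b$current, grid)
  sqrt(mean((da - db)^2))
}

#' Scan dilation factors against a reference temperature
#'
#' Reproduces the factor-selection procedure: simulate the reference current
#' at `t_reference` under the undilated protocol; then for each candidate
#' factor `f`, simulate at `t_room` under the `f`-dilated protocol, apply the
#' time/current correction, and integrate. The selected factor minimizes the
#' absolute discrepancy between corrected repolarization power and the
#' reference value; ties are broken towards the smaller factor (shorter
#' protocols are experimentally cheaper). The RMS trace discrepancy against
#' the reference is reported alongside but does not drive selection.
#'
#' @param model a [gating_model()] (any `t_ref`; it is rescaled internally
#'   with [scale_for_temperature()] to each requested temperature).
#' @param protocol the undilated [voltage_protocol()].
#' @param t_reference reference temperature, degrees C (e.g. 37).
#' @param t_room recording temperature, degrees C (e.g. 27 or 22).
#' @param factors candidate dilation factors, all > 0.
#' @param solver_reltol,solver_abstol solver tolerances.
#' @return An object of class `factor_scan` with fields `factors`,
#'   `repower_by_factor`, `reference_repower`, `discrepancy_by_factor`,
#'   `rms_by_factor`, `best_factor`, `t_reference`, `t_room`.
#' @export
scan_factors <- function(model, protocol, t_reference, t_room, factors,
                         solver_reltol = 1e-8, solver_abstol = 1e-10) {
  if (!is.numeric(factors) || length(factors) < 1L || any(factors <= 0))
    stop_field("factors", "must be positive numbers")
  m_ref <- scale_for_temperature(model, t_reference)
  m_room <- scale_for_temperature(model, t_room)
  ref_trace <- simulate_current(m_ref, protocol, solver_reltol, solver_abstol)
  ref_rp <- repolarization_power(ref_trace)$value
  rp <- rms <- numeric(length(factors))
  for (k in seq_along(factors)) {
    f <- factors[k]
    tr <- simulate_current(m_room, dilate(protocol, f),
                           solver_reltol, solver_abstol)
    cor <- correct_trace(tr, f)
    rp[k] <- repolarization_power(cor)$value
    rms[k] <- trace_discrepancy(cor, ref_trace)
  }
  disc <- abs(rp - ref_rp)
  best <- min(factors[disc == min(disc)])  # ties -> smaller factor
  structure(
    list(factors = factors,
         repower_by_factor = stats::setNames(rp, factors),
         reference_repower = ref_rp,
         discrepancy_by_factor = stats::setNames(disc, factors),
         rms_by_factor = stats::setNames(rms, factors),
         best_factor = best,
         t_reference = t_reference, t_room = t_room),
    class = "factor_scan")
}

#' @export
print.factor_scan <- function(x, ...) {
  cat(sprintf(
    "<factor_scan> reference %.4g pA.s at %g C; room %g C\n",
    x$reference_repower, x$t_reference, x$t_room))
  df <- data.frame(factor = x$factors,
                   repower = unname(x$repower_by_factor),
                   discrepancy = unname(x$discrepancy_by_factor),
                   rms = unname(x$rms_by_factor))
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("  selected factor: %g\n", x$best_factor))
  invisible(x)
}

#' Blank the late inward contamination artifact
#'
#' Optionally zeroes current samples that are both below a negative threshold
#' and within the terminal fraction of the sweep, removing the inward
#' contamination component before integration. Off by default in every
#' analysis: the standard repolarization power integrates the recorded
#' current as-is.
#'
#' @param trace a [current_trace()].
#' @param terminal_fraction fraction of the sweep (from the end) in which
#'   blanking may apply, in (0, 1].
#' @param threshold negative current threshold, pA; samples below it are
#'   zeroed.
#' @return The modified [current_trace()].
#' @export
blank_late_artifact <- function(trace, terminal_fraction = 0.3,
                                threshold = 0) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  check_scalar(terminal_fraction, "terminal_fraction", positive = TRUE)
  if (terminal_fraction > 1)
    stop_field("terminal_fraction", "must be <= 1")
  t <- trace$times
  t_on <- t[length(t)] - terminal_fraction * (t[length(t)] - t[1L])
  sel <- t >= t_on & trace$current < threshold
  out <- trace
  out$current[sel] <- 0
  out$meta$blanked_late_artifact <- TRUE
  out
}
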