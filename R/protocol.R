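#' Voltage-clamp command protocols
#'
#' A `voltage_protocol` is a sampled command waveform for an AP-clamp
#' experiment: a time grid in milliseconds starting at zero and the
#' corresponding command voltages in millivolts. The waveform starts and ends
#' at the holding potential. `dilation_factor` records by how much the time
#' axis has been stretched relative to the standard (factor-1) protocol.
#'
#' @param times numeric vector, ms, strictly increasing from 0.
#' @param voltages numeric vector, mV, same length as `times`.
#' @param holding_potential holding potential, mV; the waveform must start and
#'   end at this value.
#' @param dilation_factor positive scalar; 1 for an undilated protocol.
#' @param label free-text label.
#' @return An object of class `voltage_protocol`.
#' @seealso [build_ap_waveform()], [dilate()]
#' @export
voltage_protocol <- function(times, voltages, holding_potential,
                             dilation_factor = 1, label = "") {
  if (!is.numeric(times) || length(times) < 2L)
    stop_field("times", "need at least two samples")
  if (times[1L] != 0) stop_field("times", "must start at 0")
  if (any(diff(times) <= 0)) stop_field("times", "must be strictly increasing")
  if (length(voltages) != length(times))
    stop_field("voltages", "must match length of times")
  check_scalar(holding_potential, "holding_potential")
  check_scalar(dilation_factor, "dilation_factor", positive = TRUE)
  if (!isTRUE(all.equal(voltages[1L], holding_potential)) ||
      !isTRUE(all.equal(voltages[length(voltages)], holding_potential)))
    stop_field("voltages", "waveform must start and end at holding_potential")
  structure(
    list(times = as.numeric(times), voltages = as.numeric(voltages),
         holding_potential = holding_potential,
         dilation_factor = dilation_factor, label = as.character(label)),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol> %s\n  %d samples, %.1f ms, hold %.1f mV, dilation x%g\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$times), max(x$times), x$holding_potential, x$dilation_factor))
  invisible(x)
}

#' Parameters of the stylized ventricular action-potential waveform
#'
#' Describes a human ventricular AP envelope used as the AP-clamp command:
#' holding segment, fast linear upstroke to the peak, early repolarization to
#' the plateau, slow plateau decline, terminal (phase-3) repolarization
#' reaching 90% of the peak-to-hold amplitude at `apd90`, then relaxation back
#' to hold during the post-hold segment. Defaults are a standard human
#' ventricular AP: hold -80 mV, peak +40 mV, plateau +20 mV, APD90 300 ms.
#'
#' @param holding_potential mV.
#' @param peak_voltage mV, upstroke peak; must exceed `plateau_voltage`.
#' @param upstroke_duration ms, duration of the depolarizing upstroke.
#' @param plateau_voltage mV, early-plateau level.
#' @param apd90 ms, duration from upstroke start to 90% repolarization.
#' @param repolarization_shape `"spline"` (cosine-smoothed segments) or
#'   `"linear"` (piecewise linear).
#' @param pre_hold,post_hold ms of holding before/after the AP.
#' @param sample_interval ms between samples.
#' @return An object of class `ap_shape_params`.
#' @export
ap_shape_params <- function(holding_potential = -80, peak_voltage = 40,
                            upstroke_duration = 2, plateau_voltage = 20,
                            apd90 = 300,
                            repolarization_shape = c("spline", "linear"),
                            pre_hold = 100, post_hold = 100,
                            sample_interval = 0.5) {
  repolarization_shape <- match.arg(repolarization_shape)
  check_scalar(holding_potential, "holding_potential")
  check_scalar(peak_voltage, "peak_voltage")
  check_scalar(plateau_voltage, "plateau_voltage")
  check_scalar(upstroke_duration, "upstroke_duration", positive = TRUE)
  check_scalar(apd90, "apd90", positive = TRUE)
  check_scalar(sample_interval, "sample_interval", positive = TRUE)
  check_scalar(pre_hold, "pre_hold", nonneg = TRUE)
  check_scalar(post_hold, "post_hold", nonneg = TRUE)
  if (apd90 <= upstroke_duration)
    stop_field("apd90", "must exceed upstroke_duration")
  if (!(peak_voltage > plateau_voltage))
    stop_field("peak_voltage", "must exceed plateau_voltage")
  if (!(plateau_voltage > holding_potential))
    stop_field("plateau_voltage", "must exceed holding_potential")
  structure(
    list(holding_potential = holding_potential, peak_voltage = peak_voltage,
         upstroke_duration = upstroke_duration,
         plateau_voltage = plateau_voltage, apd90 = apd90,
         repolarization_shape = repolarization_shape,
         pre_hold = pre_hold, post_hold = post_hold,
         sample_interval = sample_interval),
    class = "ap_shape_params")
}

#' Build the AP-clamp command waveform
#'
#' Constructs the sampled command protocol from its shape parameters. The
#' voltage rises monotonically from hold to peak over the upstroke, decays to
#' the plateau, declines slowly, then repolarizes steeply so that the 90%
#' repolarization level is reached exactly at `apd90` after the upstroke
#' start; the remaining 10% relaxes to hold over the first part of the
#' post-hold segment (at most 20 ms), so the protocol ends at hold.
#'
#' @param params an [ap_shape_params()] object.
#' @return A [voltage_protocol()] with `dilation_factor = 1` and total
#'   duration `pre_hold + apd90 + post_hold` (up to one sample interval).
#' @export
build_ap_waveform <- function(params) {
  if (!inherits(params, "ap_shape_params"))
    stop_field("params", "must be an ap_shape_params object")
  p <- params
  hold <- p$holding_potential
  tau <- p$apd90 - p$upstroke_duration
  v90 <- p$peak_voltage - 0.9 * (p$peak_voltage - hold)
  # end of plateau decline sits 35% of the way from plateau down to hold
  v3 <- p$plateau_voltage - 0.35 * (p$plateau_voltage - hold)
  t_end <- p$pre_hold + p$apd90 + p$post_hold
  times <- seq(0, t_end, by = p$sample_interval)
  smooth <- p$repolarization_shape == "spline"
  ramp <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    if (smooth) (1 - cos(pi * x)) / 2 else x
  }
  t1 <- p$pre_hold
  t2 <- t1 + p$upstroke_duration
  t3 <- t2 + 0.08 * tau            # end of early repolarization
  t4 <- t2 + 0.70 * tau            # end of plateau decline
  t5 <- t1 + p$apd90               # 90% repolarization
  t6 <- t5 + min(20, p$post_hold / 2)  # settled back at hold
  v <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    v[k] <-
      if (t < t1) hold
      else if (t < t2) hold + (p$peak_voltage - hold) * (t - t1) / p$upstroke_duration
      else if (t < t3) p$peak_voltage + (p$plateau_voltage - p$peak_voltage) * ramp((t - t2) / (t3 - t2))
      else if (t < t4) p$plateau_voltage + (v3 - p$plateau_voltage) * (t - t3) / (t4 - t3)
      else if (t < t5) v3 + (v90 - v3) * ramp((t - t4) / (t5 - t4))
      else if (t < t6) v90 + (hold - v90) * ramp((t - t5) / (t6 - t5))
      else hold
  }
  v[length(v)] <- hold
  voltage_protocol(times, v, holding_potential = hold, dilation_factor = 1,
                   label = sprintf("AP apd90=%gms", p$apd90))
}

#' Dilate a protocol's time axis
#'
#' Stretches the whole command waveform (including the holding segments)
#' uniformly by `factor`: result times are `factor` times the input times,
#' voltages are unchanged, and the protocol's `dilation_factor` is multiplied
#' by `factor`.
#'
#' @param protocol a [voltage_protocol()].
#' @param factor positive dilation factor.
#' @return The dilated [voltage_protocol()].
#' @export
dilate <- function(protocol, factor) {
  if (!inherits(protocol, "voltage_protocol"))
    stop_field("protocol", "must be a voltage_protocol")
  check_scalar(factor, "factor", positive = TRUE)
  out <- protocol
  out$times <- protocol$times * factor
  out$dilation_factor <- protocol$dilation_factor * factor
  out
}

#' Write / read a protocol as two-column CSV
#'
#' The file carries a `# key=value` header block (holding_potential,
#' dilation_factor, label) followed by `time_ms,voltage_mV` columns.
#'
#' @param protocol a [voltage_protocol()].
#' @param path file path.
#' @return `write_protocol_csv` returns `path` invisibly; `read_protocol_csv`
#'   returns a [voltage_protocol()].
#' @export
write_protocol_csv <- function(protocol, path) {
  if (!inherits(protocol, "voltage_protocol"))
    stop_field("protocol", "must be a voltage_protocol")
  hdr <- c(sprintf("# holding_potential=%.17g", protocol$holding_potential),
           sprintf("# dilation_factor=%.17g", protocol$dilation_factor),
           sprintf("# label=%s", protocol$label),
           "time_ms,voltage_mV")
  rows <- sprintf("%.17g,%.17g", protocol$times, protocol$voltages)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_header(lines)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L || body[1L] != "time_ms,voltage_mV")
    stop("expected 'time_ms,voltage_mV' column header in ", path, call. = FALSE)
  dat <- utils::read.csv(text = body)
  voltage_protocol(dat$time_ms, dat$voltage_mV,
                   holding_potential = as.numeric(meta$holding_potential),
                   dilation_factor = as.numeric(meta$dilation_factor),
                   label = if (is.null(meta$label)) "" else meta$label)
}

# parse "# key=value" lines into a named list
parse_hash_header <- function(lines) {
  hdr <- lines[startsWith(lines, "#")]
  out <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}
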