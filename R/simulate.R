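#' Current traces
#'
#' A `current_trace` is a sampled time/current record, either simulated or
#' loaded from file: times in ms, current in pA (or pA/pF when
#' `density_normalized`), plus recording metadata (temperature, dilation
#' factor of the protocol it was evoked by, cell identity, and a free-form
#' `meta` list for seeds, model labels and the like).
#'
#' @param times numeric, ms, strictly increasing.
#' @param current numeric, pA (pA/pF if `density_normalized`), same length.
#' @param temperature recording temperature, degrees C (> 0 on the absolute
#'   scale is not required; positive Celsius values are expected).
#' @param dilation_factor dilation factor of the evoking protocol, > 0.
#' @param cell_id free-text cell identifier.
#' @param density_normalized logical; `TRUE` if current is per picofarad.
#' @param meta named list of extra metadata.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(times, current, temperature, dilation_factor = 1,
                          cell_id = "", density_normalized = FALSE,
                          meta = list()) {
  if (!is.numeric(times) || length(times) < 2L)
    stop_field("times", "need at least two samples")
  if (any(diff(times) <= 0)) stop_field("times", "must be strictly increasing")
  if (length(current) != length(times))
    stop_field("current", "must match length of times")
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(dilation_factor, "dilation_factor", positive = TRUE)
  structure(
    list(times = as.numeric(times), current = as.numeric(current),
         temperature = temperature, dilation_factor = dilation_factor,
         cell_id = as.character(cell_id),
         density_normalized = isTRUE(density_normalized),
         meta = meta),
    class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %s\n  %d samples, %.1f ms, %.1f C, dilation x%g, peak %.3g %s\n",
    if (nzchar(x$cell_id)) x$cell_id else "(anonymous cell)",
    length(x$times), max(x$times), x$temperature, x$dilation_factor,
    max(x$current), if (x$density_normalized) "pA/pF" else "pA"))
  invisible(x)
}

#' Simulate the hERG current under a voltage protocol
#'
#' Integrates the two gating ODEs
#' \deqn{da/dt = \alpha(V)(1-a) - \beta(V)a, \quad
#'       di/dt = r(V)(1-i) - s(V)i}
#' along the command waveform (piecewise-linear in time) with a stiff-capable
#' solver (`deSolve::lsoda`) and returns
#' \eqn{I(t) = g_{max} a^n i (V - E_{rev})} sampled on the protocol's own
#' time grid. Gates start at their steady state for the holding potential.
#' The caller is expected to have brought the model to the intended
#' temperature with [scale_for_temperature()] first; the trace records
#' `model$t_ref` as its temperature.
#'
#' @param model a [gating_model()].
#' @param protocol a [voltage_protocol()].
#' @param solver_reltol,solver_abstol solver tolerances.
#' @param cell_id cell identifier stored in the trace.
#' @return A [current_trace()] on the protocol's time grid.
#' @export
simulate_current <- function(model, protocol,
                             solver_reltol = 1e-8, solver_abstol = 1e-10,
                             cell_id = "sim") {
  sol <- solve_gates(model, protocol, solver_reltol, solver_abstol)
  curr <- model$g_max * sol$a^model$activation_exponent * sol$i *
    (protocol$voltages - model$e_rev)
  current_trace(protocol$times, curr,
                temperature = model$t_ref,
                dilation_factor = protocol$dilation_factor,
                cell_id = cell_id,
                meta = list(model = model$label,
                            solver_reltol = solver_reltol,
                            solver_abstol = solver_abstol))
}

# integrate the gate ODEs; returns gate trajectories on the protocol grid
solve_gates <- function(model, protocol, reltol, abstol) {
  vf <- stats::approxfun(protocol$times, protocol$voltages, rule = 2)
  ap <- model$activation_rate_params
  ip <- model$inactivation_rate_params
  rhs <- function(t, y, parms) {
    v <- vf(t)
    al <- ap[["A"]] * exp(ap[["B"]] * v)
    be <- ap[["C"]] * exp(-ap[["D"]] * v)
    s <- ip[["A"]] * exp(ip[["B"]] * v)
    r <- ip[["C"]] * exp(-ip[["D"]] * v)
    list(c(al * (1 - y[1L]) - be * y[1L],
           r * (1 - y[2L]) - s * y[2L]))
  }
  ss <- gate_steady_state(model, protocol$voltages[1L])
  y0 <- c(a = ss$a, i = ss$i)
  out <- deSolve::lsoda(y0, protocol$times, rhs, parms = NULL,
                        rtol = reltol, atol = abstol)
  if (nrow(out) < length(protocol$times)) {
    stop(sprintf("gating ODE solver failed at t = %.6g ms",
                 out[nrow(out), 1L]), call. = FALSE)
  }
  list(a = out[, 2L], i = out[, 3L])
}

#' Recording-artifact parameters
#'
#' Phenomenological description of the non-channel components seen in
#' automated patch-clamp recordings: Gaussian sample noise, an ohmic leak,
#' and a small late inward contamination current that ramps in over the
#' terminal fraction of the sweep (as observed when the intracellular
#' solution is contaminated by extracellular solution during the cell-catch
#' process).
#'
#' @param noise_sd Gaussian noise standard deviation, pA.
#' @param leak_conductance ohmic leak conductance, nS.
#' @param leak_reversal leak reversal potential, mV.
#' @param contamination_amplitude magnitude (pA, positive number) of the late
#'   inward component; the added current is negative.
#' @param contamination_onset_fraction fraction of the sweep (in (0, 1])
#'   after which the contamination ramps in.
#' @param rng_seed integer seed for the noise.
#' @return An object of class `artifact_params`.
#' @export
artifact_params <- function(noise_sd = 0, leak_conductance = 0,
                            leak_reversal = 0, contamination_amplitude = 0,
                            contamination_onset_fraction = 0.7,
                            rng_seed = 1L) {
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(leak_conductance, "leak_conductance", nonneg = TRUE)
  check_scalar(leak_reversal, "leak_reversal")
  check_scalar(contamination_amplitude, "contamination_amplitude", nonneg = TRUE)
  check_scalar(contamination_onset_fraction, "contamination_onset_fraction")
  if (contamination_onset_fraction <= 0 || contamination_onset_fraction > 1)
    stop_field("contamination_onset_fraction", "must be in (0, 1]")
  check_scalar(rng_seed, "rng_seed")
  structure(list(noise_sd = noise_sd, leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal,
                 contamination_amplitude = contamination_amplitude,
                 contamination_onset_fraction = contamination_onset_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "artifact_params")
}

#' Add recording artifacts to a simulated trace
#'
#' Adds, in order: the ohmic leak `g_leak * (V - E_leak)` evaluated on the
#' protocol's voltage, a late inward contamination component (smooth cosine
#' ramp from zero at the onset time to `-contamination_amplitude` at the end
#' of the sweep), and seeded Gaussian noise. The trace and protocol must
#' share the same time grid. The seed used is recorded in the trace metadata.
#'
#' @param trace a [current_trace()].
#' @param params an [artifact_params()].
#' @param protocol the [voltage_protocol()] the trace was recorded under.
#' @return The modified [current_trace()].
#' @export
add_artifacts <- function(trace, params, protocol) {
  if (!inherits(trace, "current_trace")) stop_field("trace", "must be a current_trace")
  if (!inherits(params, "artifact_params")) stop_field("params", "must be artifact_params")
  if (!inherits(protocol, "voltage_protocol")) stop_field("protocol", "must be a voltage_protocol")
  if (length(trace$times) != length(protocol$times) ||
      any(trace$times != protocol$times))
    stop("trace and protocol time grids differ", call. = FALSE)
  out <- trace
  curr <- trace$current
  curr <- curr + params$leak_conductance * (protocol$voltages - params$leak_reversal)
  if (params$contamination_amplitude > 0) {
    t0 <- trace$times[1L]
    span <- trace$times[length(trace$times)] - t0
    t_on <- t0 + params$contamination_onset_fraction * span
    x <- (trace$times - t_on) / (span * (1 - params$contamination_onset_fraction))
    x <- pmin(pmax(x, 0), 1)
    curr <- curr - params$contamination_amplitude * (1 - cos(pi * x)) / 2
  }
  if (params$noise_sd > 0) {
    curr <- curr + withr::with_seed(params$rng_seed,
      stats::rnorm(length(curr), sd = params$noise_sd))
  }
  out$current <- curr
  out$meta$artifact_seed <- params$rng_seed
  out$meta$noise_sd <- params$noise_sd
  out
}

#' Simulate a population of cells
#'
#' Draws per-cell maximal conductances from a log-normal distribution with
#' mean `model$g_max` and coefficient of variation `conductance_cv`
#' (the log-normal is mean-parameterized: `meanlog = log(g_max) - sigma^2/2`
#' with `sigma^2 = log(1 + cv^2)`), simulates each cell under the protocol,
#' and applies artifacts with per-cell seeds derived deterministically from
#' `rng_seed`. Because the current is exactly linear in `g_max`, the gating
#' ODEs are solved once and each cell's current is obtained by scaling.
#'
#' @param model a [gating_model()] (already at the intended temperature).
#' @param protocol a [voltage_protocol()].
#' @param n_cells number of cells, >= 1.
#' @param conductance_cv coefficient of variation of `g_max`, >= 0.
#' @param artifacts an [artifact_params()]; its `rng_seed` is ignored in
#'   favour of per-cell seeds derived from `rng_seed`.
#' @param rng_seed integer master seed.
#' @return A list of `n_cells` [current_trace()] objects.
#' @export
simulate_population <- function(model, protocol, n_cells,
                                conductance_cv = 0,
                                artifacts = artifact_params(),
                                rng_seed = 1L) {
  check_scalar(n_cells, "n_cells", positive = TRUE)
  check_scalar(conductance_cv, "conductance_cv", nonneg = TRUE)
  n_cells <- as.integer(n_cells)
  base <- simulate_current(model, protocol)
  g <- if (conductance_cv > 0) {
    sigma <- sqrt(log(1 + conductance_cv^2))
    withr::with_seed(as.integer(rng_seed),
      stats::rlnorm(n_cells, meanlog = log(model$g_max) - sigma^2 / 2,
                    sdlog = sigma))
  } else rep(model$g_max, n_cells)
  lapply(seq_len(n_cells), function(k) {
    tr <- base
    tr$current <- base$current * (g[k] / model$g_max)
    tr$cell_id <- sprintf("cell_%03d", k)
    tr$meta$g_max <- g[k]
    tr$meta$population_seed <- as.integer(rng_seed)
    cell_params <- artifacts
    cell_params$rng_seed <- as.integer(rng_seed) + 1000L + k
    add_artifacts(tr, cell_params, protocol)
  })
}
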