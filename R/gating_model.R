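#' hERG gating model with Q10 temperature scaling
#'
#' A Hodgkin--Huxley-style description of the macroscopic hERG (IKr) current,
#' \deqn{I = g_{max}\, a^{n}\, i\, (V - E_{rev}),}
#' with a slow activation gate `a` (raised to the power
#' `activation_exponent`, approximating the channel's multiple closed-state
#' transitions) and a fast inactivation gate `i` (fraction of non-inactivated
#' channels). Each gate follows first-order kinetics with voltage-dependent
#' exponential rate laws:
#' activation \eqn{\alpha(V) = A e^{BV}}, deactivation
#' \eqn{\beta(V) = C e^{-DV}} (per subunit), and likewise inactivation
#' \eqn{s(V) = A e^{BV}} (towards the inactivated state) and recovery
#' \eqn{r(V) = C e^{-DV}}. Rates are in ms^-1, voltages in mV.
#'
#' Temperature enters through Q10 coefficients: each named gating process and
#' the maximal conductance are multiplied by `Q10^((T - t_ref)/10)` when the
#' model is rescaled with [scale_for_temperature()].
#'
#' @param activation_rate_params named numeric `c(A=,B=,C=,D=)` for the
#'   activation gate (A: activation prefactor, ms^-1; B: its voltage slope,
#'   mV^-1; C: deactivation prefactor; D: its slope). A and C must be >= 0
#'   (zero disables the process, used for reduced models); the default model
#'   has all four strictly positive.
#' @param inactivation_rate_params same structure for the inactivation gate
#'   (A,B: inactivation; C,D: recovery).
#' @param g_max maximal conductance, nS (or nS/pF for density-normalized
#'   work); must be >= 0.
#' @param e_rev reversal potential, mV.
#' @param t_ref temperature at which the rate parameters apply, degrees C.
#' @param q10_conductance Q10 of the whole-cell conductance.
#' @param q10_rates named numeric with entries `activation`, `deactivation`,
#'   `inactivation`, `recovery`; all > 0.
#' @param activation_exponent positive integer power on the activation gate.
#' @param label free-text label.
#' @return An object of class `gating_model`.
#' @seealso [default_wt_model()], [scale_for_temperature()], [apply_variant()]
#' @export
gating_model <- function(activation_rate_params, inactivation_rate_params,
                         g_max, e_rev, t_ref = 37,
                         q10_conductance = 1.4,
                         q10_rates = c(activation = 2.2, deactivation = 2.6,
                                       inactivation = 1.9, recovery = 2.2),
                         activation_exponent = 1, label = "") {
  chk_rates <- function(x, field) {
    if (!is.numeric(x) || !all(c("A", "B", "C", "D") %in% names(x)))
      stop_field(field, "must be named numeric with A, B, C, D")
    if (any(!is.finite(x[c("A", "B", "C", "D")])))
      stop_field(field, "coefficients must be finite")
    if (x[["A"]] < 0 || x[["C"]] < 0)
      stop_field(field, "prefactors A and C must be >= 0")
    x[c("A", "B", "C", "D")]
  }
  act <- chk_rates(activation_rate_params, "activation_rate_params")
  inact <- chk_rates(inactivation_rate_params, "inactivation_rate_params")
  check_scalar(g_max, "g_max", nonneg = TRUE)
  check_scalar(e_rev, "e_rev")
  check_scalar(t_ref, "t_ref")
  check_scalar(q10_conductance, "q10_conductance", positive = TRUE)
  procs <- c("activation", "deactivation", "inactivation", "recovery")
  if (!is.numeric(q10_rates) || !all(procs %in% names(q10_rates)))
    stop_field("q10_rates", "must name activation, deactivation, inactivation, recovery")
  if (any(q10_rates[procs] <= 0)) stop_field("q10_rates", "values must be > 0")
  check_scalar(activation_exponent, "activation_exponent", positive = TRUE)
  structure(
    list(activation_rate_params = act, inactivation_rate_params = inact,
         g_max = g_max, e_rev = e_rev, t_ref = t_ref,
         q10_conductance = q10_conductance, q10_rates = q10_rates[procs],
         activation_exponent = activation_exponent,
         label = as.character(label)),
    class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf(
    "<gating_model> %s\n  g_max %.4g nS, E_rev %.1f mV, t_ref %.1f C, a^%g i\n  Q10 cond %.2g; rates %s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$g_max, x$e_rev, x$t_ref, x$activation_exponent, x$q10_conductance,
    paste(sprintf("%s %.2g", names(x$q10_rates), x$q10_rates), collapse = ", ")))
  invisible(x)
}

# exponential rate-law coefficients from interpretable anchors:
# half-activation voltage, steady-state slope (mV per e-fold), and the gate
# time constant at an anchor voltage. B and D share the slope symmetrically.
rate_coeffs_from_anchors <- function(v_half, slope, tau_anchor, v_anchor) {
  b <- 1 / (2 * slope)
  a <- 1
  cc <- exp((2 * b) * v_half)           # forward == backward at v_half
  s <- a * exp(b * v_anchor) + cc * exp(-b * v_anchor)
  a <- (1 / tau_anchor) / s
  c(A = a, B = b, C = a * exp((2 * b) * v_half), D = b)
}

#' Default wild-type hERG model
#'
#' The packaged wild-type parameterization at 37 degrees C. Activation uses
#' four identical slow subunit transitions (`a^4`), half-activation -30 mV
#' with a 9 mV slope and a per-subunit time constant of 500 ms at +20 mV;
#' inactivation is fast (4 ms at 0 mV) with half-voltage -55 mV and a shallow
#' 25 mV slope. The reversal potential is -88 mV (physiological K+ gradient)
#' and `g_max` (3200 nS) is an effective scaling constant calibrated so the
#' wild-type repolarization power under the default AP clamp at 37 degrees C
#' is about 22 pA.s; it is not a literature whole-cell conductance, because
#' the model operates far below saturating open probability during a single
#' AP. Q10 defaults: conductance 1.4; activation 2.2, deactivation 2.6,
#' inactivation 1.9, recovery 2.2 (all within the published 1.7--2.6 range
#' for hERG gating rates).
#'
#' @return A [gating_model()] at `t_ref = 37`.
#' @export
default_wt_model <- function() {
  act <- rate_coeffs_from_anchors(v_half = -30, slope = 9,
                                  tau_anchor = 500, v_anchor = 20)
  inact <- rate_coeffs_from_anchors(v_half = -55, slope = 25,
                                    tau_anchor = 4, v_anchor = 0)
  gating_model(
    activation_rate_params = act,
    inactivation_rate_params = inact,
    g_max = 3200, e_rev = -88, t_ref = 37,
    q10_conductance = 1.4,
    q10_rates = c(activation = 2.2, deactivation = 2.6,
                  inactivation = 1.9, recovery = 2.2),
    activation_exponent = 4, label = "WT hERG (default)")
}

#' Gating rates and steady states
#'
#' `gating_rates` evaluates the four voltage-dependent rate laws;
#' `gate_steady_state` returns the per-subunit activation and the
#' availability (non-inactivated fraction) at steady state.
#'
#' @param model a [gating_model()].
#' @param v voltage(s), mV.
#' @return `gating_rates`: list with vectors `activation`, `deactivation`,
#'   `inactivation`, `recovery` (ms^-1). `gate_steady_state`: list with
#'   vectors `a` (per-subunit activation) and `i` (availability).
#' @export
gating_rates <- function(model, v) {
  ap <- model$activation_rate_params
  ip <- model$inactivation_rate_params
  list(activation = ap[["A"]] * exp(ap[["B"]] * v),
       deactivation = ap[["C"]] * exp(-ap[["D"]] * v),
       inactivation = ip[["A"]] * exp(ip[["B"]] * v),
       recovery = ip[["C"]] * exp(-ip[["D"]] * v))
}

#' @rdname gating_rates
#' @export
gate_steady_state <- function(model, v) {
  r <- gating_rates(model, v)
  a_den <- r$activation + r$deactivation
  i_den <- r$recovery + r$inactivation
  list(a = ifelse(a_den > 0, r$activation / a_den, 1),
       i = ifelse(i_den > 0, r$recovery / i_den, 1))
}

#' Rescale a model to a different temperature
#'
#' Applies the Q10 law `x(T) = x(t_ref) * Q10^((T - t_ref)/10)` to each named
#' gating process (activation, deactivation, inactivation, recovery) and to
#' the maximal conductance, and stamps the result with the new temperature.
#'
#' @param model a [gating_model()].
#' @param temperature target temperature, degrees C, within 15--40 (guard
#'   against extrapolating the Q10 law).
#' @return The rescaled [gating_model()] with `t_ref == temperature`.
#' @export
scale_for_temperature <- function(model, temperature) {
  if (!inherits(model, "gating_model"))
    stop_field("model", "must be a gating_model")
  check_scalar(temperature, "temperature")
  if (temperature < 15 || temperature > 40)
    stop_field("temperature", "must be within [15, 40] degrees C")
  dt10 <- (temperature - model$t_ref) / 10
  q <- model$q10_rates
  out <- model
  out$activation_rate_params[["A"]] <-
    model$activation_rate_params[["A"]] * q[["activation"]]^dt10
  out$activation_rate_params[["C"]] <-
    model$activation_rate_params[["C"]] * q[["deactivation"]]^dt10
  out$inactivation_rate_params[["A"]] <-
    model$inactivation_rate_params[["A"]] * q[["inactivation"]]^dt10
  out$inactivation_rate_params[["C"]] <-
    model$inactivation_rate_params[["C"]] * q[["recovery"]]^dt10
  out$g_max <- model$g_max * model$q10_conductance^dt10
  out$t_ref <- temperature
  out
}

#' Variant presets
#'
#' A `variant_preset` describes a channel variant phenomenologically: a
#' conductance scale, per-process rate scales, and a shift of the
#' inactivation voltage dependence. `hERG_variant` returns the packaged
#' presets: `"WT"` (identity), `"R328C"` (loss of function: conductance
#' scaled to 0.3, as for a trafficking/expression-deficient LQTS-linked
#' variant) and `"D591H"` (gain of function: inactivation half-voltage
#' shifted +30 mV and recovery from inactivation doubled, as for an
#' SQTS-linked attenuated-inactivation variant).
#'
#' @param name preset name.
#' @param conductance_scale multiplier on `g_max`, >= 0.
#' @param rate_scales named numeric multipliers for `activation`,
#'   `deactivation`, `inactivation`, `recovery`; all > 0.
#' @param inactivation_vhalf_shift mV shift of the inactivation voltage
#'   dependence (positive = towards depolarized potentials, i.e. less
#'   inactivation).
#' @return An object of class `variant_preset`.
#' @export
variant_preset <- function(name, conductance_scale = 1,
                           rate_scales = c(activation = 1, deactivation = 1,
                                           inactivation = 1, recovery = 1),
                           inactivation_vhalf_shift = 0) {
  check_scalar(conductance_scale, "conductance_scale", nonneg = TRUE)
  procs <- c("activation", "deactivation", "inactivation", "recovery")
  full <- stats::setNames(rep(1, 4), procs)
  if (!is.null(names(rate_scales))) full[names(rate_scales)] <- rate_scales
  if (any(!is.finite(full)) || any(full <= 0))
    stop_field("rate_scales", "values must be finite and > 0")
  check_scalar(inactivation_vhalf_shift, "inactivation_vhalf_shift")
  structure(list(name = as.character(name),
                 conductance_scale = conductance_scale,
                 rate_scales = full,
                 inactivation_vhalf_shift = inactivation_vhalf_shift),
            class = "variant_preset")
}

#' @rdname variant_preset
#' @export
hERG_variant <- function(name = c("WT", "R328C", "D591H")) {
  name <- match.arg(name)
  switch(name,
    WT = variant_preset("WT"),
    R328C = variant_preset("R328C", conductance_scale = 0.3),
    D591H = variant_preset("D591H",
                           rate_scales = c(recovery = 2),
                           inactivation_vhalf_shift = 30))
}

#' Apply a variant preset to a model
#'
#' Scales the conductance and each gating rate by the preset's factors and
#' shifts the inactivation voltage dependence by
#' `inactivation_vhalf_shift` (both inactivation and recovery rate laws are
#' evaluated at `V - shift`).
#'
#' @param model a [gating_model()].
#' @param preset a [variant_preset()].
#' @return The modified [gating_model()].
#' @export
apply_variant <- function(model, preset) {
  if (!inherits(model, "gating_model"))
    stop_field("model", "must be a gating_model")
  if (!inherits(preset, "variant_preset"))
    stop_field("preset", "must be a variant_preset")
  rs <- preset$rate_scales
  sh <- preset$inactivation_vhalf_shift
  out <- model
  out$activation_rate_params[["A"]] <-
    model$activation_rate_params[["A"]] * rs[["activation"]]
  out$activation_rate_params[["C"]] <-
    model$activation_rate_params[["C"]] * rs[["deactivation"]]
  ip <- model$inactivation_rate_params
  # V -> V - shift is an exponential prefactor change for exponential laws
  out$inactivation_rate_params[["A"]] <-
    ip[["A"]] * rs[["inactivation"]] * exp(-ip[["B"]] * sh)
  out$inactivation_rate_params[["C"]] <-
    ip[["C"]] * rs[["recovery"]] * exp(ip[["D"]] * sh)
  out$g_max <- model$g_max * preset$conductance_scale
  out$label <- sprintf("%s [%s]", model$label, preset$name)
  out
}
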