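# shared fixtures, built in code; expensive simulations are memoized so the
# same trace is computed once per test run

.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

default_protocol <- function() cached("default_protocol",
  build_ap_waveform(ap_shape_params()))

# coarser grid for tests that only need qualitative dynamics
coarse_protocol <- function() cached("coarse_protocol",
  build_ap_waveform(ap_shape_params(pre_hold = 50, post_hold = 50,
                                    sample_interval = 1)))

wt_model <- function() default_wt_model()

# model with one Q10 for every gating process (and optionally conductance)
uniform_q10_model <- function(q_rate = 2.2, q_cond = 1.4) {
  wt <- default_wt_model()
  gating_model(wt$activation_rate_params, wt$inactivation_rate_params,
               g_max = wt$g_max, e_rev = wt$e_rev, t_ref = wt$t_ref,
               q10_conductance = q_cond,
               q10_rates = c(activation = q_rate, deactivation = q_rate,
                             inactivation = q_rate, recovery = q_rate),
               activation_exponent = wt$activation_exponent,
               label = sprintf("uniform Q10 %g/%g", q_rate, q_cond))
}

wt37_trace <- function() cached("wt37_trace",
  simulate_current(wt_model(), default_protocol()))

# a simple synthetic triangular trace for integral arithmetic
triangle_trace <- function(rise_ms = 200, fall_ms = 200, peak_pa = 100,
                           dt = 1) {
  t <- seq(0, rise_ms + fall_ms, by = dt)
  cur <- ifelse(t <= rise_ms, peak_pa * t / rise_ms,
                peak_pa * (1 - (t - rise_ms) / fall_ms))
  current_trace(t, cur, temperature = 22, dilation_factor = 1,
                cell_id = "triangle")
}

# random smooth-ish trace for property tests
random_trace <- function(n = 120, dt = 2) {
  t <- seq(0, by = dt, length.out = n)
  cur <- cumsum(stats::rnorm(n))
  current_trace(t, cur, temperature = 22, dilation_factor = 1,
                cell_id = "random")
}
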