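constant_protocol <- function(v, duration = 400, dt = 2) {
  t <- seq(0, duration, by = dt)
  voltage_protocol(t, rep(v, length(t)), holding_potential = v)
}

test_that("no current flows at the reversal potential or at rest", {
  m <- default_wt_model()
  at_rev <- simulate_current(m, constant_protocol(m$e_rev))
  expect_true(all(abs(at_rev$current) < 1e-9))

  peak <- max(wt37_trace()$current)
  at_hold <- simulate_current(m, constant_protocol(-80))
  expect_lt(max(abs(at_hold$current)), 0.01 * peak)
})

test_that("trace carries temperature and dilation metadata from its inputs", {
  m <- scale_for_temperature(default_wt_model(), 27)
  tr <- simulate_current(m, dilate(coarse_protocol(), 2))
  expect_equal(tr$temperature, 27)
  expect_equal(tr$dilation_factor, 2)
  expect_equal(length(tr$times), length(tr$current))
})

test_that("single-gate step response matches the closed-form exponential relaxation", {
  wt <- default_wt_model()
  # reduced model: first-power activation, inactivation disabled (i == 1)
  m <- gating_model(wt$activation_rate_params,
                    c(A = 0, B = 0, C = 1, D = 0),
                    g_max = wt$g_max, e_rev = wt$e_rev, t_ref = 37,
                    activation_exponent = 1, label = "single gate")
  t <- seq(0, 400, by = 0.5)
  v_step <- ifelse(t < 50 | t >= 350, -80, 0)
  v_step[length(v_step)] <- -80
  prot <- voltage_protocol(t, v_step, holding_potential = -80)
  tr <- simulate_current(m, prot)

  ap <- m$activation_rate_params
  rate_at <- function(v) c(al = ap[["A"]] * exp(ap[["B"]] * v),
                           be = ap[["C"]] * exp(-ap[["D"]] * v))
  r0 <- rate_at(-80); rs <- rate_at(0)
  a0 <- r0[["al"]] / (r0[["al"]] + r0[["be"]])
  ainf <- rs[["al"]] / (rs[["al"]] + rs[["be"]])
  tau <- 1 / (rs[["al"]] + rs[["be"]])
  on_step <- t >= 50 & t < 350
  a_closed <- ainf + (a0 - ainf) * exp(-(t[on_step] - 50) / tau)
  i_closed <- m$g_max * a_closed * (0 - m$e_rev)
  err <- max(abs(tr$current[on_step] - i_closed)) / max(abs(i_closed))
  expect_lt(err, 1e-3)
})

test_that("artifact injection behaves as documented", {
  prot <- coarse_protocol()
  tr <- cached("coarse_wt", simulate_current(default_wt_model(), prot))

  none <- add_artifacts(tr, artifact_params(), prot)
  expect_equal(none$times, tr$times)
  expect_equal(none$current, tr$current)

  p <- artifact_params(noise_sd = 5, rng_seed = 99)
  n1 <- add_artifacts(tr, p, prot)
  n2 <- add_artifacts(tr, p, prot)
  expect_identical(n1$current, n2$current)  # seeded determinism
  expect_false(identical(n1$current, tr$current))

  cont <- add_artifacts(tr, artifact_params(contamination_amplitude = 100,
                                            contamination_onset_fraction = 0.7),
                        prot)
  late <- cont$times >= 0.8 * max(cont$times)
  expect_lt(min(cont$current[late]), 0)  # late segment dips inward
  delta <- cont$current - tr$current
  expect_true(all(delta <= 0))           # added component is inward-only
  expect_true(all(delta[cont$times <= 0.7 * max(cont$times)] == 0))
  expect_equal(delta[length(delta)], -100)

  leak <- add_artifacts(tr, artifact_params(leak_conductance = 0.5,
                                            leak_reversal = 0), prot)
  expect_equal(leak$current - tr$current, 0.5 * (prot$voltages - 0))

  bad <- tr; bad$times <- tr$times + 1
  expect_error(add_artifacts(bad, p, prot), "grid")
})

test_that("population simulation is deterministic and mean-preserving", {
  m <- default_wt_model()
  prot <- coarse_protocol()
  single <- cached("coarse_wt", simulate_current(m, prot))

  one <- simulate_population(m, prot, n_cells = 1, conductance_cv = 0,
                             rng_seed = 3)
  expect_equal(one[[1L]]$current, single$current)

  pop <- simulate_population(m, prot, n_cells = 50, conductance_cv = 0.3,
                             rng_seed = 17)
  expect_length(pop, 50L)
  rp <- vapply(pop, function(tr) repolarization_power(tr)$value, numeric(1))
  rp0 <- repolarization_power(single)$value
  expect_lt(abs(mean(rp) - rp0) / rp0, 0.10)  # mean-parameterized log-normal

  pop2 <- simulate_population(m, prot, n_cells = 50, conductance_cv = 0.3,
                              rng_seed = 17)
  expect_identical(lapply(pop, `[[`, "current"),
                   lapply(pop2, `[[`, "current"))
})

test_that("corrected simulation under uniform slowing reproduces the reference exactly", {
  # all Q10s (rates and conductance) equal to the dilation factor: cooling by
  # 10 C then dilating time by that factor is an exact change of variables
  f <- 2
  u <- uniform_q10_model(q_rate = f, q_cond = f)
  prot <- default_protocol()
  ref <- cached("rescaling_ref", simulate_current(u, prot))
  room <- scale_for_temperature(u, u$t_ref - 10)
  cor <- correct_trace(simulate_current(room, dilate(prot, f)), f)
  expect_equal(cor$times, ref$times, tolerance = 1e-12)
  err <- max(abs(cor$current - ref$current)) / max(abs(ref$current))
  expect_lt(err, 1e-3)
})

test_that("tightening solver tolerances leaves the repolarization power unchanged", {
  prot <- default_protocol()
  m <- default_wt_model()
  rp <- repolarization_power(wt37_trace())$value
  rp_tight <- repolarization_power(
    simulate_current(m, prot, solver_reltol = 1e-9,
                     solver_abstol = 1e-11))$value
  expect_lt(abs(rp_tight - rp) / rp, 1e-4)
})
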