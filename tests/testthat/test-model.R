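test_that("default model is closed at hold and carries the published conductance Q10", {
  m <- default_wt_model()
  expect_equal(m$q10_conductance, 1.4)
  expect_true(all(m$q10_rates >= 1.7 & m$q10_rates <= 2.6))
  # steady-state activation at -80 mV from the stored rate constants
  ap <- m$activation_rate_params
  al <- ap[["A"]] * exp(ap[["B"]] * -80)
  be <- ap[["C"]] * exp(-ap[["D"]] * -80)
  expect_lt(al / (al + be), 0.01)
  expect_equal(gate_steady_state(m, -80)$a, al / (al + be))
  # rates finite and positive across the physiological range
  r <- gating_rates(m, seq(-120, 60, by = 5))
  for (v in r) expect_true(all(is.finite(v) & v > 0))
})

test_that("open-channel current vanishes at the reversal potential", {
  m <- default_wt_model()
  v <- m$e_rev
  ss <- gate_steady_state(m, v)
  expect_equal(m$g_max * ss$a^m$activation_exponent * ss$i * (v - m$e_rev), 0)
})

test_that("Q10 scaling follows the closed form and is transitive", {
  m <- default_wt_model()
  expect_equal(scale_for_temperature(m, m$t_ref), m)

  u <- uniform_q10_model(q_rate = 2, q_cond = 1.4)
  down <- scale_for_temperature(u, u$t_ref - 10)
  expect_equal(down$activation_rate_params[["A"]],
               u$activation_rate_params[["A"]] / 2)
  expect_equal(down$inactivation_rate_params[["C"]],
               u$inactivation_rate_params[["C"]] / 2)
  expect_equal(down$g_max, u$g_max / 1.4)
  expect_equal(down$t_ref, u$t_ref - 10)

  two_step <- scale_for_temperature(scale_for_temperature(m, 27), 22)
  one_step <- scale_for_temperature(m, 22)
  expect_equal(two_step$activation_rate_params,
               one_step$activation_rate_params, tolerance = 1e-10)
  expect_equal(two_step$inactivation_rate_params,
               one_step$inactivation_rate_params, tolerance = 1e-10)
  expect_equal(two_step$g_max, one_step$g_max, tolerance = 1e-10)

  expect_error(scale_for_temperature(m, 10), "temperature")
  expect_error(scale_for_temperature(m, 45), "temperature")
})

test_that("variant presets act as documented on the model parameters", {
  m <- default_wt_model()
  ident <- variant_preset("null", conductance_scale = 1,
                          inactivation_vhalf_shift = 0)
  m2 <- apply_variant(m, ident)
  expect_equal(m2$activation_rate_params, m$activation_rate_params)
  expect_equal(m2$inactivation_rate_params, m$inactivation_rate_params)
  expect_equal(m2$g_max, m$g_max)

  r328c <- apply_variant(m, hERG_variant("R328C"))
  expect_equal(r328c$g_max, 0.3 * m$g_max)
  expect_equal(r328c$activation_rate_params, m$activation_rate_params)

  # +30 mV shift moves the availability curve right by exactly 30 mV
  d591h <- apply_variant(m, variant_preset("shift-only",
                                           inactivation_vhalf_shift = 30))
  v <- seq(-80, 20, by = 10)
  expect_equal(gate_steady_state(d591h, v)$i,
               gate_steady_state(m, v - 30)$i, tolerance = 1e-12)
})

test_that("zero conductance yields identically zero current", {
  m <- apply_variant(default_wt_model(),
                     variant_preset("dead", conductance_scale = 0))
  tr <- simulate_current(m, coarse_protocol())
  expect_true(all(tr$current == 0))
})

test_that("repolarization power is linear (hence strictly increasing) in g_max", {
  m <- default_wt_model()
  prot <- coarse_protocol()
  rp1 <- repolarization_power(simulate_current(m, prot))$value
  m2 <- m; m2$g_max <- 2 * m$g_max
  rp2 <- repolarization_power(simulate_current(m2, prot))$value
  expect_equal(rp2, 2 * rp1, tolerance = 1e-8)
  expect_gt(rp2, rp1)
})

test_that("malformed model parameters are rejected", {
  m <- default_wt_model()
  expect_error(gating_model(c(A = 1, B = 1), m$inactivation_rate_params,
                            g_max = 1, e_rev = -88),
               "activation_rate_params")
  expect_error(gating_model(m$activation_rate_params,
                            m$inactivation_rate_params,
                            g_max = -1, e_rev = -88), "g_max")
  expect_error(gating_model(m$activation_rate_params,
                            m$inactivation_rate_params, g_max = 1,
                            e_rev = -88,
                            q10_rates = c(activation = 1)), "q10_rates")
})
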