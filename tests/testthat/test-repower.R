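test_that("repolarization power computes elementary integrals exactly", {
  t <- seq(0, 500, by = 1)
  const <- current_trace(t, rep(10, length(t)), temperature = 22)
  expect_equal(repolarization_power(const)$value, 5)        # 10 pA x 0.5 s

  zero <- current_trace(t, rep(0, length(t)), temperature = 22)
  expect_equal(repolarization_power(zero)$value, 0)

  expect_equal(repolarization_power(triangle_trace())$value, 20)  # triangle area

  # negative excursions integrate with sign
  neg <- current_trace(t, rep(-10, length(t)), temperature = 22)
  expect_equal(repolarization_power(neg)$value, -5)
})

test_that("integration windows are honoured, interpolated, and validated", {
  tr <- triangle_trace()
  expect_equal(repolarization_power(tr, 0, 200)$value, 10)
  # endpoints between samples are linearly interpolated
  half <- repolarization_power(tr, 0.5, 200)$value
  expect_equal(half, 10 - 0.5 * 0.5 * (100 / 200) / 1000 * 0.5, tolerance = 1e-6)
  expect_error(repolarization_power(tr, -10, 100), "outside")
  expect_error(repolarization_power(tr, 0, 1000), "outside")
  expect_error(repolarization_power(tr, 100, 100), "window_end")
})

test_that("the time/current correction preserves the integral for any factor", {
  tr <- triangle_trace()
  expect_equal(correct_trace(tr, 1)$times, tr$times)
  expect_equal(correct_trace(tr, 1)$current, tr$current)

  withr::with_seed(4, {
    for (k in 1:25) {
      raw <- random_trace()
      f <- stats::runif(1, 0.5, 5)
      dil <- raw
      dil$times <- raw$times * f
      dil$dilation_factor <- f
      cor <- correct_trace(dil, f)
      rp_cor <- repolarization_power(cor)$value
      rp_raw_dilated <- repolarization_power(dil)$value
      expect_equal(rp_cor, rp_raw_dilated, tolerance = 1e-12)
    }
  })

  expect_warning(correct_trace(triangle_trace(), 2), "dilation_factor")
  expect_error(correct_trace(triangle_trace(), 0), "factor")
})

test_that("time of peak finds the maximum, breaking ties early", {
  expect_equal(time_of_peak(triangle_trace()), 200)
  flat_top <- current_trace(0:10, c(0, 1, 2, 3, 3, 3, 2, 1, 0, 0, 0),
                            temperature = 22)
  expect_equal(time_of_peak(flat_top), 3)  # earliest of the tied maxima
  degen <- current_trace(0:5, rep(2, 6), temperature = 22)
  expect_warning(tp <- time_of_peak(degen), "degenerate")
  expect_equal(tp, 0)
})

test_that("peak normalization is idempotent and scale-invariant", {
  tr <- triangle_trace()
  norm <- normalize_to_peak(tr)
  expect_equal(max(norm$current), 1)
  expect_equal(normalize_to_peak(norm)$current, norm$current)
  scaled <- tr; scaled$current <- 3.7 * tr$current
  expect_equal(normalize_to_peak(scaled)$current, norm$current)
  neg <- current_trace(0:5, rep(-1, 6), temperature = 22)
  expect_error(normalize_to_peak(neg), "maximum")
})

test_that("trace discrepancy measures RMS difference over the overlap", {
  tr <- triangle_trace()
  expect_equal(trace_discrepancy(tr, tr), 0)
  shifted <- tr; shifted$current <- tr$current + 7
  expect_equal(trace_discrepancy(tr, shifted), 7)
  far <- current_trace(c(1000, 1001), c(0, 0), temperature = 22)
  expect_error(trace_discrepancy(tr, far), "overlap")
})

test_that("factor scan with no temperature gap selects factor 1 exactly", {
  s <- scan_factors(default_wt_model(), coarse_protocol(),
                    t_reference = 37, t_room = 37, factors = c(1, 2))
  expect_equal(s$best_factor, 1)
  expect_lt(s$discrepancy_by_factor[["1"]], 1e-8 * s$reference_repower)
  expect_equal(unname(s$discrepancy_by_factor[as.character(s$best_factor)]),
               min(s$discrepancy_by_factor))
  expect_error(scan_factors(default_wt_model(), coarse_protocol(),
                            37, 27, c(1, -2)), "factors")
})

test_that("late-artifact blanking removes only late negative samples", {
  t <- seq(0, 100, by = 1)
  cur <- c(rep(5, 60), rep(-3, 41))
  tr <- current_trace(t, cur, temperature = 22)
  bl <- blank_late_artifact(tr, terminal_fraction = 0.3, threshold = 0)
  expect_true(all(bl$current[t >= 70] == 0))
  expect_equal(bl$current[t < 70], cur[t < 70])
})
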