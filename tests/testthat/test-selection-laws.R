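# Closed-form selection laws: division program, Tfh intensity, schedules.

test_that("division program has its half-effect at x = K", {
  expect_equal(n_divisions(1, K = 1), 3.5, tolerance = 1e-12)
  expect_equal(n_divisions(7.1, K = 7.1), 3.5, tolerance = 1e-12)
  expect_equal(n_divisions(0, K = 1), 1)
  expect_equal(n_divisions(1e9, K = 1), 6, tolerance = 1e-6)
  # K = 0 (assumption A4 baseline): any positive input earns n_max
  expect_equal(n_divisions(0.01, K = 0), 6)
  expect_equal(n_divisions(0, K = 0), 1)
  # non-decreasing in x for fixed K
  x <- seq(0, 30, by = 0.25)
  expect_true(all(diff(n_divisions(x, K = 4)) >= 0))
})

test_that("Tfh signal intensity has J = 1.5 at the half-effect density", {
  expect_equal(tfh_intensity(7.1), 1.5, tolerance = 1e-12)
  expect_equal(tfh_intensity(0), 0)
  expect_equal(tfh_intensity(1e9), 3, tolerance = 1e-6)
  expect_true(all(diff(tfh_intensity(seq(0, 40, 0.5))) >= 0))
})

test_that("decay schedules halve at t = K and are monotone", {
  expect_equal(tmax_schedule(600, K_T = 600), 0.5, tolerance = 1e-12)
  expect_equal(tmax_schedule(0, K_T = 600), 1)
  expect_equal(kext_schedule(150, K_ext = 150), 0.5 / 36, tolerance = 1e-12)
  expect_equal(kext_schedule(0, K_ext = 150), 1 / 36)
  tt <- seq(0, 1000, 5)
  expect_true(all(diff(tmax_schedule(tt, 400)) <= 0))
  # disabled schedule (control): constant
  expect_equal(tmax_schedule(tt, Inf), rep(1, length(tt)))
})

test_that("division constant grows with DZ-LZ cycles under capacity exhaustion", {
  expect_equal(division_K(0, 1, 25, K_K = 5), 1)
  expect_equal(division_K(5, 1, 25, K_K = 5), 13, tolerance = 1e-12)
  expect_equal(division_K(1e6, 1, 25, K_K = 5), 25, tolerance = 1e-3)
  n <- 0:40
  expect_true(all(diff(division_K(n, 1, 25, 5)) >= 0))
  # larger K at fixed input means fewer divisions
  expect_true(all(diff(sapply(c(1, 5, 15, 25), function(K) n_divisions(4, K))) < 0))
  # control: K stays at K_min
  expect_equal(division_K(n, 1, 25, Inf), rep(1, length(n)))
})

test_that("terminal differentiation probabilities behave per their laws", {
  expect_equal(diff_prob_hill(3, K_F = 3), 0.5)
  expect_equal(diff_prob_hill(0, K_F = 3), 0)
  expect_equal(diff_prob_time(0:1000, k = 0), rep(0, 1001))
  expect_equal(diff_prob_time(1e6, k = 0.003), 1, tolerance = 1e-9)
  tt <- seq(0, 504, 4)
  expect_true(all(diff(diff_prob_time(tt, 0.003)) > 0))
})
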