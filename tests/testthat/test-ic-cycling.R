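# Immune-complex cycling between FDC surface and interior.

test_that("constant-rate cycling relaxes to the analytic steady state", {
  # k_int = 1/21 /min, k_ext = 1/36 /min -> surface fraction 21/57
  phi <- ic_surface_fraction(times = c(1, 2, 5, 10), phi0 = 1)
  expect_equal(phi[4], 21 / 57, tolerance = 1e-4)
  # full trajectory matches the closed-form exponential relaxation
  ki <- 60 / 21
  ke <- 60 / 36
  lam <- ki + ke
  tt <- seq(0.1, 3, by = 0.1)
  closed <- ke / lam + (1 - ke / lam) * exp(-lam * tt)
  expect_equal(ic_surface_fraction(tt, phi0 = 1), closed, tolerance = 1e-4)
})

test_that("modulated externalization drives the surface fraction down", {
  tt <- seq(1, 504, by = 1)
  phi <- ic_surface_fraction(tt, K_ext = 150)
  # starts at the steady state of the initial rates, then declines
  expect_equal(phi[1], 21 / 57, tolerance = 1e-3)
  expect_true(all(diff(phi) <= 1e-12))
  expect_lt(phi[length(phi)], 0.05)
  # disabled schedule stays at steady state
  phi0 <- ic_surface_fraction(tt, K_ext = Inf)
  expect_equal(phi0, rep(21 / 57, length(tt)), tolerance = 1e-6)
})
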