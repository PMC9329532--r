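# Antibody feedback module: bins, production/decay ODE, masking, immune power.

test_that("bins span the dissociation-constant range log-uniformly", {
  b <- antibody_bins()
  expect_identical(nrow(b), 11L)
  expect_equal(b$K_D[1], 10^-5.5)
  expect_equal(b$K_D[11], 10^-9.5)
  expect_equal(diff(log10(b$K_D)), rep(-0.4, 10), tolerance = 1e-12)
  expect_equal(b$k_off, b$k_on * b$K_D)
})

test_that("affinity maps to bins log-linearly with correct endpoints", {
  b <- antibody_bins()
  expect_identical(bin_of_affinity(0, b), 1L)     # K_D = 1e-5.5, lowest affinity
  expect_identical(bin_of_affinity(1, b), 11L)    # K_D = 1e-9.5, highest
  expect_identical(bin_of_affinity(0.5, b), 6L)   # middle bin
  expect_error(bin_of_affinity(1.2, b))
})

test_that("antibody concentration follows the production-decay ODE", {
  # steady state k1 n_p / (V k2)
  pool <- antibody_pool()
  pool$n_p[5] <- 100L
  for (i in 1:2000) pool <- antibody_step(pool, 24)
  expect_equal(pool$A[5], pool$k1 * 100 / (pool$volume_l * pool$k2_per_h),
               tolerance = 1e-4)
  # pure decay: halves every 14 days
  pool2 <- antibody_pool()
  pool2$A[3] <- 1e-9
  for (i in 1:14) pool2 <- antibody_step(pool2, 24)
  expect_equal(pool2$A[3], 0.5e-9, tolerance = 1e-4)
  # production with decay disabled: one plasma cell for 1 h in 10 ml
  # secretes k1 = 3e-18 mol
  pool3 <- antibody_pool(k2_per_h = 0)
  pool3$n_p[1] <- 1L
  for (i in 1:100) pool3 <- antibody_step(pool3, 0.01)
  expect_equal(pool3$A[1] * pool3$volume_l, 3e-18, tolerance = 1e-6)
})

test_that("output cells differentiate into plasma cells with a 24-h half-life", {
  set.seed(11)
  fit <- plasma_halflife_fit(n_cells = 20000, hours = 72, dt_h = 0.5)
  expect_equal(fit$half_life_h, 24, tolerance = 0.02)
  # counts are conserved between pending and plasma pools
  tr <- fit$trajectory
  expect_true(all(tr$pending + tr$n_plasma == 20000))
})

test_that("masking equilibrium and immune power closed forms hold", {
  expect_equal(mask_equilibrium(1e-9, K_D = 1e-9, N = 1), 0.5)
  expect_equal(mask_equilibrium(0, K_D = 1e-9), 0)
  # N = 0 disables masking entirely
  expect_equal(mask_equilibrium(1e-6, K_D = 1e-9, N = 0), 0)
  # single bin with K = R: IP = A / (2R)
  R <- 1e-5
  A <- 3e-8
  expect_equal(immune_power(A, K_D = R, R = R), A / (2 * R), tolerance = 1e-12)
  # saturation limit K << R: IP -> sum(A)/R
  expect_equal(immune_power(c(A, A), K_D = c(1e-12, 1e-12), R = R),
               2 * A / R, tolerance = 1e-6)
  # zero antibody -> zero immune power
  expect_equal(immune_power(numeric(11), antibody_bins()$K_D), 0)
})

test_that("immune power is monotone in concentrations and affinities", {
  KD <- antibody_bins()$K_D
  A <- rep(1e-9, 11)
  ip0 <- immune_power(A, KD)
  for (i in c(1, 6, 11)) {
    A2 <- A
    A2[i] <- A[i] * 2
    expect_gt(immune_power(A2, KD), ip0)
  }
  # tightening every K_D (higher affinity) cannot decrease IP
  expect_gte(immune_power(A, KD / 10), ip0)
  expect_equal(ip_fold_change(2, 4), 0.5)
})
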