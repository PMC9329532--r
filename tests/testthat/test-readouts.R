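# Readout normalization, peak detection, time-point comparisons.

test_that("peak detection smooths stochastic argmax instability", {
  t <- 0:100
  v <- c(seq(0, 50, length.out = 41), seq(50, 30, length.out = 60))
  v[20] <- 80  # an isolated spike should not win after smoothing
  pk <- gc_peak(v, t, smooth_h = 6)
  expect_gt(pk$t_peak, 30)
  expect_lt(pk$t_peak, 50)
})

test_that("normalization modes behave as ratios with NA on zero reference", {
  x <- c(2, 4, 8)
  expect_equal(normalize_readouts(x, c(2, 2, 2)), c(1, 2, 4))
  expect_equal(normalize_readouts(x, 4), c(0.5, 1, 2))       # peak mode
  expect_true(is.na(normalize_readouts(c(1, 2), c(1, 0))[2]))
  # a series normalized to its own peak value is 1 at the peak
  v <- c(1, 3, 9, 5)
  expect_equal(normalize_readouts(v, v[3])[3], 1)
})

test_that("time-point comparison is a symmetric rank-sum test", {
  set.seed(21)
  x <- rnorm(50)
  y <- rnorm(50, mean = 5)
  r1 <- compare_timepoints(x, y)
  expect_lt(r1$p_value, 0.001)
  expect_identical(r1$stars, "***")
  expect_equal(compare_timepoints(y, x)$p_value, r1$p_value)
  same <- rep(1, 10)
  expect_identical(compare_timepoints(same, same)$stars, "NS")
  expect_error(compare_timepoints(1:2, 1:5), "at least 3")
})

test_that("per-replicate peak-offset extraction has the right shape", {
  cfg <- mini_config(duration_days = 3)
  reps <- gc_replicates(cfg, n = 3, seed = 10)
  m <- readout_at_peak_offsets(reps, "volume", offsets_days = c(0, 1),
                               window_h = 6)
  expect_identical(dim(m), c(3L, 2L))
  expect_true(all(is.finite(m[, 1])))
  # values at the peak are near each replicate's own around-peak volume
  expect_true(all(m[, 1] > 0))
})
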