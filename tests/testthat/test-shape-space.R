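# Shape space: Gaussian affinity and neighbor mutations.

test_that("affinity follows the Gaussian distance law", {
  e <- c(5, 5, 5, 5)
  expect_identical(shape_affinity(e, e), 1)
  # d = gamma -> exp(-1); checked against a hand evaluation of the Gaussian
  expect_equal(shape_affinity(c(5, 5, 5, 5 + 2.8), e, gamma = 2.8), exp(-1),
               tolerance = 1e-12)
  # monotone decay with distance, symmetric in arguments
  d <- sapply(0:5, function(k) shape_affinity(e + c(k, 0, 0, 0), e))
  expect_true(all(diff(d) < 0))
  expect_equal(shape_affinity(c(1, 2, 3, 4), e), shape_affinity(e, c(1, 2, 3, 4)))
  # translation invariance
  off <- c(2, -1, 3, 0)
  expect_equal(shape_affinity(c(1, 2, 3, 4) + off, e + off),
               shape_affinity(c(1, 2, 3, 4), e))
  # far tail approaches zero
  expect_lt(shape_affinity(c(0, 0, 0, 0), c(9, 9, 9, 9)), 1e-10)
  expect_error(shape_affinity(c(1, 2, 3), e), "4 coordinates")
})

test_that("mutation shifts exactly one coordinate by one, within bounds", {
  set.seed(1)
  p <- c(4, 5, 3, 6)
  m <- shape_mutate(p, n = 500)
  d <- abs(sweep(m, 2, p))
  expect_true(all(rowSums(d) == 1))
  expect_true(all(d %in% c(0, 1)))
  expect_true(all(m >= 0 & m <= 9))
  # at a corner only in-bounds neighbors are produced
  m0 <- shape_mutate(c(0, 0, 0, 0), n = 200)
  expect_true(all(m0 >= 0))
})

test_that("mutation directions are uniform over admissible neighbors", {
  # interior point: 8 neighbors, each ~1/8 of draws (chi-square)
  set.seed(2)
  p <- c(4, 4, 4, 4)
  n <- 2e4
  m <- shape_mutate(p, n = n)
  key <- apply(m, 1, paste, collapse = ",")
  tab <- table(key)
  expect_length(tab, 8)
  chi <- sum((tab - n / 8)^2 / (n / 8))
  expect_lt(chi, qchisq(0.999, df = 7))
  # the engine's internal mutation kernel has the same law
  me <- cpp_mutate_draws(p, n, 0L, 9L, seed = 7)
  tab2 <- table(apply(me, 1, paste, collapse = ","))
  expect_length(tab2, 8)
  chi2 <- sum((tab2 - n / 8)^2 / (n / 8))
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("founder receptors fall in the configured distance band", {
  set.seed(3)
  ep <- matrix(c(5, 5, 5, 5), nrow = 1)
  f <- founder_points(300, ep, dmin = 2, dmax = 5)
  d <- sqrt(rowSums(sweep(f, 2, ep[1, ])^2))
  expect_true(all(d >= 2 & d <= 5))
  expect_true(all(f >= 0 & f <= 9))
})
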