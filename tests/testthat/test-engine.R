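# Engine orchestration: configuration validation, determinism, replicate
# summaries, ledger conservation, mechanism/control pairing at small scale.

test_that("configuration validation rejects inconsistent requests", {
  expect_error(gc_config("control", "A1", K_K = 5), "M7")
  expect_error(gc_config("M5", "A1", k_c = 0.2), "M3")
  expect_error(gc_config("control", "A1", radius_um = 2))
  expect_error(gc_config("control", "A1", dt_h = 0.05),
               "resolve")  # dt must resolve the uptake interval
  expect_error(gc_config("control", "A1", nonsense = 1), "unknown")
  cfg <- gc_config("M7", "A2", K_K = 8)
  expect_identical(cfg$K_K, 8)
  expect_identical(cfg$K_min, 1)   # A2 division constant
  cfg4 <- gc_config("control", "A4")
  expect_identical(cfg4$K_min, 0)
})

test_that("identical configuration and seed reproduce a run bitwise", {
  cfg <- mini_config(duration_days = 3)
  r1 <- gc_simulate(cfg, seed = 123)
  r2 <- gc_simulate(cfg, seed = 123)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$counters, r2$counters)
  expect_identical(r1$antibody$A, r2$antibody$A)
  r3 <- gc_simulate(cfg, seed = 124)
  expect_false(identical(r3$timeseries$volume, r1$timeseries$volume))
})

test_that("hourly output covers the full duration including t = 0", {
  run <- gc_simulate(mini_config(duration_days = 2), seed = 1)
  expect_identical(nrow(run$timeseries), 49L)
  expect_identical(run$timeseries$t[1], 0)
  expect_identical(run$timeseries$t[49], 48)
})

test_that("replicate summaries have matching shape and honest dispersion", {
  cfg <- mini_config(duration_days = 2)
  reps <- gc_replicates(cfg, n = 4, seed = 99)
  expect_identical(nrow(reps$mean), 49L)
  expect_identical(dim(reps$array)[3], 4L)
  expect_identical(reps$seeds, replicate_seeds(99, 4))
  # forcing identical seeds gives zero dispersion
  r1 <- gc_simulate(cfg, seed = 7)$timeseries$volume
  r2 <- gc_simulate(cfg, seed = 7)$timeseries$volume
  expect_identical(stats::sd(c(r1[40], r2[40])), 0)
  # mean lies within the replicate envelope
  expect_true(all(reps$mean$volume <= apply(reps$array[, "volume", ], 1, max)))
})

test_that("antigen ledger is conserved under consumption and masking", {
  # M1: remaining + consumed = initial
  run <- gc_simulate(mini_config("M1", duration_days = 5), seed = 2)
  ts <- run$timeseries
  init <- ts$ag_total[1]
  expect_gt(run$counters$consumed, 0)
  expect_equal(ts$ag_total + ts$ag_consumed, rep(init, nrow(ts)),
               tolerance = 1e-6)
  # M2: free + masked + interior partitions the retained antigen
  run2 <- gc_simulate(mini_config("M2", duration_days = 5,
                                  ab_feedback_N = 2000), seed = 2)
  ts2 <- run2$timeseries
  expect_equal(ts2$ag_free + ts2$ag_masked + ts2$ag_interior, ts2$ag_total,
               tolerance = 1e-6)
  expect_gt(max(ts2$ag_masked), 0)
  # masking never exceeds the retained antigen
  expect_true(all(ts2$ag_masked <= ts2$ag_total + 1e-9))
})

test_that("neutral mechanism parameters reproduce control behavior", {
  cfg_ctl <- mini_config("control", duration_days = 3)
  # M2 with N = 0 has masking scaled away entirely: same trajectory as the
  # control for the same seed
  cfg_m2 <- mini_config("M2", duration_days = 3, ab_feedback_N = 0)
  expect_identical(gc_simulate(cfg_ctl, seed = 31)$timeseries$volume,
                   gc_simulate(cfg_m2, seed = 31)$timeseries$volume)
  # M5 with K_T = Inf: constant signaling capacity, identical to control
  cfg_m5 <- mini_config("M5", duration_days = 3, K_T = Inf)
  expect_identical(gc_simulate(cfg_ctl, seed = 31)$timeseries$volume,
                   gc_simulate(cfg_m5, seed = 31)$timeseries$volume)
  # M6 time-dependent with k = 0: F = 0, everyone recycles
  cfg_m6 <- mini_config("M6c", duration_days = 4, k_diff = 0)
  run <- gc_simulate(cfg_m6, seed = 5)
  expect_identical(run$counters$outputs_differentiation, 0)
  fr <- run$timeseries$frac_recycled
  expect_true(all(is.na(fr) | fr == 1))
})

test_that("FDC dendrites grow and contract with antigen conserved", {
  cfg <- mini_config("M3", duration_days = 10, k_c = 0.332,
                     fdc_switch_h = 96)
  run <- gc_simulate(cfg, seed = 3)
  ts <- run$timeseries
  sites <- ts$fdc_sites
  # growth phase: non-decreasing site count until the switch
  expect_true(all(diff(sites[1:95]) >= 0))
  # contraction phase: non-increasing afterwards
  expect_true(all(diff(sites[100:nrow(ts)]) <= 0))
  # redistribution conserves the total
  expect_equal(ts$ag_total, rep(ts$ag_total[1], nrow(ts)), tolerance = 1e-6)
  # growth-only control never loses sites
  run0 <- gc_simulate(mini_config("M3", duration_days = 10, k_c = 0,
                                  fdc_switch_h = 96), seed = 3)
  expect_true(all(diff(run0$timeseries$fdc_sites) >= 0))
})

test_that("two-epitope antigen is supported with per-epitope antibody pools", {
  cfg <- mini_config(duration_days = 4,
                     epitopes = matrix(c(5L, 5L, 5L, 5L,
                                         2L, 7L, 3L, 6L), nrow = 2, byrow = TRUE),
                     epitope_fractions = c(0.9, 0.1))
  run <- gc_simulate(cfg, seed = 17)
  expect_identical(dim(run$antibody$A), c(2L, 11L))
  expect_equal(run$timeseries$ag_total[1], 20 * 3000)
  expect_gt(run$timeseries$volume[97], 0)
})

test_that("run artifacts can be written and read back", {
  run <- gc_simulate(mini_config(duration_days = 1), seed = 1, events = TRUE)
  pre <- file.path(tempdir(), "gcrun")
  files <- gc_write(run, pre)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(paste0(pre, "_timeseries.csv"))
  expect_identical(nrow(back), nrow(run$timeseries))
  meta <- jsonlite::read_json(paste0(pre, "_meta.json"))
  expect_identical(meta$mechanism, "control")
  expect_identical(meta$seed, 1L)
  unlink(files)
})
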