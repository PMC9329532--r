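# B cell life cycle measured from small simulations and their event logs.

test_that("founders arrive at 2/h for 4 days and carry 6 divisions", {
  # no FDCs: every founder runs through its division program and dies at the
  # end of the collection window, leaving the division tree fully observable
  cfg <- mini_config(n_fdc = 0L, duration_days = 6, influx_window_h = 96)
  founders <- divisions <- daughters <- numeric(3)
  for (s in 1:3) {
    run <- gc_simulate(cfg, seed = s, events = TRUE)
    founders[s] <- run$counters$founders
    divisions[s] <- run$counters$divisions
    daughters[s] <- run$counters$daughters
    ev <- run$events
    expect_true(all(ev$t[ev$type == "influx"] <= 96))
    expect_true(all(ev$aux[ev$type == "influx"] == 6L))
  }
  # Poisson(2/h x 96 h): mean 192, accept within 3 SE across runs
  se <- sqrt(192 / 3)
  expect_lt(abs(mean(founders) - 192), 3 * se)
  # binary tree of depth 6: 63 divisions and 126 daughters per founder
  expect_identical(divisions, founders * 63)
  expect_identical(daughters, founders * 126)
})

test_that("daughters mutate with probability one half", {
  run <- gc_simulate(mini_config(n_fdc = 0L, duration_days = 5), seed = 9)
  frac <- run$counters$mutated_daughters / run$counters$daughters
  n <- run$counters$daughters
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("72% of antigen-carrying divisions are asymmetric and spawn output", {
  run <- gc_simulate(mini_config(duration_days = 8), seed = 4)
  nd <- run$counters$divisions_with_antigen
  expect_gt(nd, 200)
  frac <- run$counters$asymmetric_divisions / nd
  expect_lt(abs(frac - 0.72), 3 * sqrt(0.72 * 0.28 / nd))
  # each asymmetric division hands the antigen to an exiting output daughter
  expect_identical(run$counters$outputs_asymmetric,
                   run$counters$asymmetric_divisions)
})

test_that("antigen collection respects window and spacing constraints", {
  run <- gc_simulate(mini_config(duration_days = 5), seed = 6, events = TRUE)
  ev <- run$events
  up <- ev[ev$type == "uptake", ]
  expect_gt(nrow(up), 100)
  by_cell <- split(up$t, up$cell)
  gaps <- unlist(lapply(by_cell, function(t) diff(sort(t))))
  # no two collection events of one cell closer than 0.02 h
  expect_true(all(gaps >= 0.02 - 1e-9))
  # within one collection window (recycled cells open several), events span
  # at most 0.7 h; windows of one cell are separated by hours
  spans <- unlist(lapply(by_cell, function(t) {
    t <- sort(t)
    win <- cumsum(c(0, diff(t) > 0.75))
    tapply(t, win, function(x) max(x) - min(x))
  }))
  expect_true(all(spans <= 0.7 + 0.011))
  # cells that failed to capture antigen die; capture leads to the
  # FDC-selected stage
  deaths <- ev[ev$type == "death" & ev$aux == 0, ]
  expect_true(all(deaths$v1 == 0))  # p = 0 at collection death
})

test_that("selection requires 0.5 h of integrated Tfh signal within 3 h", {
  run <- gc_simulate(mini_config(duration_days = 6), seed = 8, events = TRUE)
  ev <- run$events
  sel <- ev[ev$type == "selection", ]
  expect_gt(nrow(sel), 30)
  expect_true(all(sel$v2 >= 0.5))              # T_sig at selection
  tfh_death <- ev[ev$type == "death" & ev$aux == 1, ]
  expect_gt(nrow(tfh_death), 10)
  expect_true(all(tfh_death$v2 < 0.5))
  # individual contacts last 6 minutes
  cs <- ev[ev$type == "contact_start", ]
  ce <- ev[ev$type == "contact_end", ]
  shared <- intersect(cs$cell, ce$cell)[1:20]
  for (id in shared[!is.na(shared)]) {
    t0 <- cs$t[cs$cell == id][1]
    t1 <- ce$t[ce$cell == id]
    t1 <- min(t1[t1 > t0])
    expect_lte(t1 - t0, 0.1 + 0.011)
  }
})

test_that("division numbers follow the program and recycled cells re-divide", {
  run <- gc_simulate(mini_config(duration_days = 6), seed = 12, events = TRUE)
  ev <- run$events
  rec <- ev[ev$type == "recycle", ]
  expect_gt(nrow(rec), 20)
  # granted divisions stay within [n_min, n_max]
  expect_true(all(rec$aux >= 1 & rec$aux <= 6))
  # stochastic rounding preserves the Hill mean: granted divisions track
  # n_divisions(p) for the recorded p values
  expected <- n_divisions(rec$v1, K = 1)
  expect_lt(abs(mean(rec$aux - expected)), 0.15)
})

test_that("population bookkeeping balances births, deaths and exits", {
  run <- gc_simulate(mini_config(duration_days = 6), seed = 3)
  ts <- run$timeseries
  ctr <- run$counters
  final_live <- ts$volume[nrow(ts)] + ts$n_state_output[nrow(ts)]
  expect_identical(ctr$founders + ctr$divisions - ctr$deaths_collection -
                     ctr$deaths_tfh - ctr$exits, final_live)
  # chemotaxis segregates the compartments: dividing cells accumulate in
  # the DZ, giving the canonical DZ-majority once the reaction is running
  expect_gt(ts$n_dz[nrow(ts)], ts$n_lz[nrow(ts)])
  # per-state counts sum to the GC volume
  sums <- ts$n_state_dz + ts$n_state_unselected + ts$n_state_fdcselected +
    ts$n_state_selected
  expect_identical(sums, ts$volume)
  # fractions stay within [0, 1]
  for (cl in c("frac_lz_selected", "frac_uptake_success", "frac_recycled",
               "frac_output", "surface_fraction")) {
    v <- ts[[cl]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)), info = cl)
  }
})
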