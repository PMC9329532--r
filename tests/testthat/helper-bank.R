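# Shared replicate banks for the mechanism suites. Built lazily on first
# use and cached for the session, so several acceptance blocks can reuse
# the same runs. All banks use the scaled 90-um profile, 21 simulated
# days, and replicate seeds derived from master seed 42.

.acc_env <- new.env(parent = emptyenv())

acc_reps <- function(key, mechanism, assumption = "A1", n = 20, ...) {
  if (is.null(.acc_env[[key]])) {
    cfg <- gc_scaled_config(mechanism, assumption, duration_days = 21, ...)
    .acc_env[[key]] <- gc_replicates(cfg, n = n, seed = 42)
  }
  .acc_env[[key]]
}

# day-21 mean volume of a replicate set
day21_volume <- function(reps) {
  mean(reps$array[nrow(reps$mean), "volume", ])
}

peak_mean_volume <- function(reps) {
  gc_peak(reps$mean$volume, reps$mean$t)$volume
}
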