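# Run orchestration: single runs, replicate sets, S3 methods.

#' Run a single germinal center simulation
#'
#' Advances all agents (B cells, Tfh cells, the FDC network), the antigen
#' ledgers and the antibody system from GC onset to the configured duration,
#' and returns hourly readout time series plus cumulative event counters.
#' Results are bitwise reproducible for a given `(config, seed)` pair; the
#' run uses its own RNG stream and does not touch R's RNG state.
#'
#' @param config a [gc_config()] object.
#' @param seed integer seed for the run's private RNG stream.
#' @param events if `TRUE`, also return a flat per-event log (influx,
#'   divisions, uptake attempts, Tfh contacts, selections, deaths, exits).
#'   Intended for small runs; the log is capped at `config$max_events` rows.
#' @return an object of class `gc_run` with elements `timeseries` (one row
#'   per hour), `counters`, `antibody`, `lattice`, `config`, `seed`, and
#'   optionally `events`.
#' @examples
#' \donttest{
#' cfg <- gc_config("control", "A1", radius_um = 60, duration_days = 2)
#' run <- gc_simulate(cfg, seed = 1)
#' head(run$timeseries[, c("t", "volume", "n_dz", "n_lz")])
#' }
#' @export
gc_simulate <- function(config, seed = 1, events = FALSE) {
  if (!inherits(config, "gc_config")) stop("config must be a gc_config object")
  res <- cpp_run_gc(cfg_to_engine(config, record_events = events),
                    as.integer(seed))
  run <- list(timeseries = res$timeseries,
              counters = res$counters,
              antibody = res$antibody,
              lattice = res$lattice,
              config = config,
              seed = as.integer(seed))
  if (events) {
    ev <- res$events
    ev$type <- c("influx", "division", "uptake", "transition",
                 "contact_start", "contact_end", "selection", "death",
                 "exit", "recycle")[ev$type]
    run$events <- ev
    if (isTRUE(res$events_truncated))
      warning("event log truncated at max_events rows")
  }
  class(run) <- "gc_run"
  run
}

#' @export
print.gc_run <- function(x, ...) {
  ts <- x$timeseries
  cat("<gc_run> mechanism ", x$config$mechanism, ", assumption ",
      x$config$assumption, ", seed ", x$seed, "\n", sep = "")
  cat("  duration: ", max(ts$t) / 24, " days (", nrow(ts), " hourly rows)\n",
      sep = "")
  pk <- which.max(ts$volume)
  cat("  GC volume: peak ", ts$volume[pk], " cells at day ",
      round(ts$t[pk] / 24, 1), "; final ", ts$volume[nrow(ts)], "\n", sep = "")
  cat("  output cells exited: ", x$counters$exits, "; plasma cells: ",
      sum(x$antibody$n_plasma), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gc_run <- function(object, ...) {
  ts <- object$timeseries
  pk <- which.max(ts$volume)
  out <- list(
    mechanism = object$config$mechanism,
    assumption = object$config$assumption,
    seed = object$seed,
    peak_volume = ts$volume[pk],
    peak_day = ts$t[pk] / 24,
    final_volume = ts$volume[nrow(ts)],
    founders = object$counters$founders,
    divisions = object$counters$divisions,
    selections = object$counters$selections,
    exits = object$counters$exits,
    immune_power = ts$immune_power[nrow(ts)]
  )
  class(out) <- "summary.gc_run"
  out
}

#' @export
print.summary.gc_run <- function(x, ...) {
  cat("GC simulation summary (", x$mechanism, ", ", x$assumption, ")\n", sep = "")
  cat(sprintf("  peak volume   : %d cells (day %.1f)\n", x$peak_volume, x$peak_day))
  cat(sprintf("  final volume  : %d cells\n", x$final_volume))
  cat(sprintf("  founders      : %d\n", as.integer(x$founders)))
  cat(sprintf("  divisions     : %d\n", as.integer(x$divisions)))
  cat(sprintf("  selections    : %d\n", as.integer(x$selections)))
  cat(sprintf("  output exits  : %d\n", as.integer(x$exits)))
  cat(sprintf("  immune power  : %.4g\n", x$immune_power))
  invisible(x)
}

#' @export
plot.gc_run <- function(x, which = "volume", ...) {
  ts <- x$timeseries
  if (!which %in% names(ts)) stop("unknown readout: ", which)
  graphics::plot(ts$t / 24, ts[[which]], type = "l", xlab = "time (days)",
                 ylab = which,
                 main = paste0(x$config$mechanism, " / ", x$config$assumption),
                 ...)
  invisible(x)
}

#' Replicate seeds derived from a master seed
#'
#' @param seed master seed.
#' @param n number of replicates.
#' @return integer vector of `n` seeds.
#' @export
replicate_seeds <- function(seed, n) {
  r <- local({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  })
  r
}

#' Run replicate simulations and summarize
#'
#' Runs `n` independent replicates (seeds derived deterministically from the
#' master seed) and computes the per-hour mean and standard deviation of
#' every readout column, as the replicate protocol behind the reported
#' mean +/- SD kinetics.
#'
#' @param config a [gc_config()] object.
#' @param n number of replicates.
#' @param seed master seed.
#' @param keep_series if `TRUE` (default) the full per-replicate readout
#'   array is kept in the result (needed for time-point comparisons).
#' @return an object of class `gc_replicates` with elements `mean`, `sd`
#'   (data.frames, one row per hour), `array` (hours x readouts x replicates,
#'   if kept), `counters` (replicates x counters), `ip` (per-replicate
#'   immune power at the final time), `seeds`, `config`.
#' @export
gc_replicates <- function(config, n = 50, seed = 1, keep_series = TRUE) {
  stopifnot(n >= 1)
  seeds <- replicate_seeds(seed, n)
  runs <- vector("list", n)
  for (i in seq_len(n)) runs[[i]] <- gc_simulate(config, seeds[i])
  ts1 <- runs[[1]]$timeseries
  cols <- setdiff(names(ts1), "t")
  arr <- array(NA_real_, dim = c(nrow(ts1), length(cols), n),
               dimnames = list(NULL, cols, NULL))
  for (i in seq_len(n))
    arr[, , i] <- as.matrix(runs[[i]]$timeseries[, cols])
  mean_df <- as.data.frame(apply(arr, c(1, 2), mean, na.rm = TRUE))
  sd_df <- if (n >= 2) as.data.frame(apply(arr, c(1, 2), stats::sd, na.rm = TRUE))
           else mean_df * NA
  mean_df <- cbind(t = ts1$t, mean_df)
  sd_df <- cbind(t = ts1$t, sd_df)
  ctr <- do.call(rbind, lapply(runs, function(r) unlist(r$counters)))
  ip <- vapply(runs, function(r) r$timeseries$immune_power[nrow(r$timeseries)],
               numeric(1))
  out <- list(mean = mean_df, sd = sd_df,
              array = if (keep_series) arr else NULL,
              counters = ctr, ip = ip, seeds = seeds, n = n, config = config)
  class(out) <- "gc_replicates"
  out
}

#' @export
print.gc_replicates <- function(x, ...) {
  pk <- which.max(x$mean$volume)
  cat("<gc_replicates> ", x$n, " replicates, mechanism ", x$config$mechanism,
      ", assumption ", x$config$assumption, "\n", sep = "")
  cat(sprintf("  mean GC volume: peak %.0f (day %.1f), final %.0f +/- %.0f\n",
              x$mean$volume[pk], x$mean$t[pk] / 24,
              x$mean$volume[nrow(x$mean)], x$sd$volume[nrow(x$sd)]))
  invisible(x)
}

#' @export
plot.gc_replicates <- function(x, which = "volume", ...) {
  t <- x$mean$t / 24
  m <- x$mean[[which]]
  s <- x$sd[[which]]
  graphics::plot(t, m, type = "n", xlab = "time (days)", ylab = which,
                 ylim = range(c(m - s, m + s), na.rm = TRUE), ...)
  graphics::polygon(c(t, rev(t)), c(m - s, rev(m + s)), border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(t, m, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Lattice geometry summary
#'
#' Enumerates the discretized spherical lattice for a given radius and
#' spacing and reports the total site count and the dark-zone / light-zone
#' partition (the two hemispheres along the chemokine axis).
#'
#' @param radius_um GC radius (micrometers).
#' @param spacing_um lattice spacing (micrometers, one cell diameter).
#' @return list with `n_sites`, `n_dz`, `n_lz`, `L` (grid side length),
#'   `sites_radius` (radius in lattice units).
#' @export
lattice_info <- function(radius_um = 160, spacing_um = 5) {
  stopifnot(spacing_um > 0, radius_um > spacing_um)
  cpp_lattice_info(radius_um, spacing_um)
}

#' Write a run to disk
#'
#' Writes the hourly time series as CSV, the event log (if recorded) as CSV,
#' and a JSON metadata block echoing the full configuration.
#'
#' @param run a `gc_run` object.
#' @param path output path prefix (files `<path>_timeseries.csv`,
#'   `<path>_events.csv`, `<path>_meta.json`).
#' @return invisibly, the vector of files written.
#' @export
gc_write <- function(run, path) {
  files <- character(0)
  f <- paste0(path, "_timeseries.csv")
  utils::write.csv(run$timeseries, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(run$events)) {
    f <- paste0(path, "_events.csv")
    utils::write.csv(run$events, f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- run$config
  class(meta) <- NULL
  meta$epitopes <- apply(meta$epitopes, 1, function(r) as.list(as.integer(r)),
                         simplify = FALSE)
  meta$seed <- run$seed
  meta$counters <- run$counters
  f <- paste0(path, "_meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
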