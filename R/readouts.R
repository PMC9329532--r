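# Diagnostic readouts: normalization, peak detection, time-point comparison.

#' Readout time series of a run
#'
#' Returns the hourly readout table of a `gc_run`: GC volume (live GC B
#' cells), DZ/LZ counts, per-state counts, the fraction of LZ B cells in the
#' Selected state, mean pMHC density and Tfh signal of cells selected in the
#' window, mean divisions of recycling cells, recycling and output fractions,
#' the fraction of successful uptake events among FDC-B encounters, FDC
#' network size per B cell, the antigen ledger (free / masked / interior /
#' consumed), the surface antigen fraction, and the antibody summary.
#' Window averages with an empty denominator are `NA`, not zero.
#'
#' @param run a `gc_run` object.
#' @return the time-series data.frame.
#' @export
gc_readouts <- function(run) {
  if (!inherits(run, "gc_run")) stop("run must be a gc_run object")
  run$timeseries
}

#' Peak of the GC reaction
#'
#' The peak time is the argmax of the (replicate-mean) GC volume after
#' smoothing with a centered moving average, guarding against stochastic
#' argmax instability.
#'
#' @param volume GC volume series (vector).
#' @param t matching time vector (hours).
#' @param smooth_h smoothing window (hours).
#' @return list with `t_peak` (hours), `index`, `volume` (smoothed peak value).
#' @export
gc_peak <- function(volume, t, smooth_h = 6) {
  w <- max(1, round(smooth_h / max(diff(t)[1], 1e-9)))
  if (w %% 2 == 0) w <- w + 1
  sm <- stats::filter(volume, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- volume[is.na(sm)]
  i <- which.max(sm)
  list(t_peak = t[i], index = i, volume = as.numeric(sm[i]))
}

#' Normalize readout series
#'
#' Two normalization modes are used for reporting: elementwise division by a
#' control series (mechanism-vs-control comparisons) or division by the
#' series' own value at the peak of the GC reaction (post-peak trend
#' panels). Zero reference values propagate `NA`.
#'
#' @param series numeric vector (one readout over time) or data.frame of
#'   readouts.
#' @param reference a numeric vector of matching length (mode `"control"`) or
#'   a single reference value (mode `"peak"`).
#' @return normalized series of the same shape.
#' @export
normalize_readouts <- function(series, reference) {
  ref <- unlist(reference)
  ref[ref == 0] <- NA_real_
  if (is.data.frame(series)) {
    as.data.frame(mapply(function(s, r) s / r, series, ref, SIMPLIFY = FALSE))
  } else {
    series / ref
  }
}

#' Compare replicate readouts between two time points
#'
#' Two-sample Wilcoxon rank-sum comparison of a readout across replicates at
#' two time points (or between a mechanism and its control at one time
#' point), with conventional significance stars.
#'
#' @param x,y numeric vectors of per-replicate values (>= 3 each).
#' @param alternative as in [stats::wilcox.test()].
#' @return list with `statistic`, `p_value`, `stars`.
#' @export
compare_timepoints <- function(x, y, alternative = "two.sided") {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 replicate values per group")
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    # degenerate: identical constant samples
    return(list(statistic = NA_real_, p_value = 1, stars = "NS"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = FALSE))
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "NS"
  list(statistic = unname(wt$statistic), p_value = p, stars = stars)
}

#' Per-replicate readout values at offsets from the GC peak
#'
#' Extracts, for every replicate, the value of a readout at the peak of the
#' replicate-mean GC volume and at day offsets after it, averaging over a
#' +/- half-window around each time point to tame hour-scale noise.
#'
#' @param reps a `gc_replicates` object (with the series array kept).
#' @param readout readout column name.
#' @param offsets_days day offsets relative to the peak.
#' @param window_h half-window (hours) averaged around each time point.
#' @return matrix: replicates x offsets.
#' @export
readout_at_peak_offsets <- function(reps, readout,
                                    offsets_days = c(0, 3, 6),
                                    window_h = 12) {
  if (is.null(reps$array)) stop("replicate series array not kept")
  t <- reps$mean$t
  pk <- gc_peak(reps$mean$volume, t)
  out <- matrix(NA_real_, dim(reps$array)[3], length(offsets_days))
  colnames(out) <- paste0("peak+", offsets_days, "d")
  for (j in seq_along(offsets_days)) {
    tc <- pk$t_peak + offsets_days[j] * 24
    sel <- which(abs(t - tc) <= window_h)
    if (length(sel) == 0) next
    vals <- reps$array[sel, readout, , drop = FALSE]
    out[, j] <- apply(vals, 3, function(v) mean(v, na.rm = TRUE))
  }
  out
}
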