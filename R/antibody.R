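# Antibody feedback module: output -> plasma differentiation, 11 affinity
# bins of soluble antibody, antigen masking, immune power.

#' Antibody affinity bins
#'
#' Soluble antibody is tracked in `n_bins` affinity bins sharing one on-rate
#' `k_on` and spanning dissociation constants log-uniformly between
#' `10^kd_lo_log10` and `10^kd_hi_log10` M; `k_off(i) = k_on * K_D(i)`.
#'
#' @param n_bins number of bins.
#' @param kd_lo_log10,kd_hi_log10 log10 dissociation constants of the lowest-
#'   and highest-affinity bins (M).
#' @param k_on association rate constant (per molar per hour).
#' @return data.frame with columns `bin`, `K_D`, `k_on`, `k_off`.
#' @export
antibody_bins <- function(n_bins = 11, kd_lo_log10 = -5.5, kd_hi_log10 = -9.5,
                          k_on = 1e6) {
  lg <- seq(kd_lo_log10, kd_hi_log10, length.out = n_bins)
  data.frame(bin = seq_len(n_bins), K_D = 10^lg, k_on = k_on,
             k_off = k_on * 10^lg)
}

#' Map an affinity to an antibody bin
#'
#' The exiting cell's affinity (in `[0, 1]`) is mapped log-linearly onto the
#' dissociation-constant range of the bins (affinity 0 -> lowest-affinity
#' bin, affinity 1 -> highest) and assigned to the nearest bin.
#'
#' @param affinity numeric in `[0, 1]`; vectorized.
#' @param bins a bin table from [antibody_bins()].
#' @return integer bin indices.
#' @export
bin_of_affinity <- function(affinity, bins = antibody_bins()) {
  if (any(affinity < 0 | affinity > 1 | !is.finite(affinity)))
    stop("affinity must lie in [0, 1]")
  as.integer(round(affinity * (nrow(bins) - 1))) + 1L
}

#' Create an antibody pool
#'
#' State container for the soluble-antibody compartment: per-bin antibody
#' concentration `A` (M), plasma cell counts `n_p`, and output cells pending
#' differentiation into plasma cells (`pending`, half-life
#' `plasma_halflife_h`). Plasma cells secrete at `k1` mol/h/cell into volume
#' `volume_l`; antibody decays at `k2_per_h`.
#'
#' @param bins bin table from [antibody_bins()].
#' @param k1 secretion rate (mol per hour per plasma cell).
#' @param k2_per_h antibody decay rate (per hour); default ln(2)/14 per day.
#' @param volume_l dilution volume (liters).
#' @param plasma_halflife_h half-life of the output-to-plasma differentiation.
#' @return an object of class `antibody_pool`.
#' @export
antibody_pool <- function(bins = antibody_bins(), k1 = 3e-18,
                          k2_per_h = log(2) / (14 * 24), volume_l = 0.01,
                          plasma_halflife_h = 24) {
  structure(list(
    bins = bins,
    A = numeric(nrow(bins)),
    n_p = integer(nrow(bins)),
    pending = integer(nrow(bins)),
    k1 = k1, k2_per_h = k2_per_h, volume_l = volume_l,
    plasma_halflife_h = plasma_halflife_h
  ), class = "antibody_pool")
}

#' @export
print.antibody_pool <- function(x, ...) {
  cat("<antibody_pool> ", nrow(x$bins), " bins; ",
      sum(x$n_p), " plasma cells, ", sum(x$pending), " pending outputs; ",
      "total antibody ", format(sum(x$A), digits = 3), " M\n", sep = "")
  invisible(x)
}

#' Add exiting output cells to an antibody pool
#'
#' @param pool an [antibody_pool()].
#' @param affinity affinities of the exiting cells (vector, values in
#'   `[0, 1]`); each cell enters the pending pool of its affinity bin.
#' @return the updated pool.
#' @export
add_output_cells <- function(pool, affinity) {
  b <- bin_of_affinity(affinity, pool$bins)
  tab <- tabulate(b, nbins = nrow(pool$bins))
  pool$pending <- pool$pending + as.integer(tab)
  pool
}

#' Advance the antibody pool by one timestep
#'
#' Pending output cells differentiate into plasma cells with per-step
#' probability `1 - exp(-ln(2) / half-life * dt)` (binomial thinning, uses
#' R's RNG); each bin's concentration then follows
#' `dA/dt = k1 / V * n_p - k2 A`, advanced with the exact exponential update
#' for the step (the closed-form solution for constant `n_p`).
#'
#' @param pool an [antibody_pool()].
#' @param dt_h timestep (hours).
#' @return the updated pool.
#' @export
antibody_step <- function(pool, dt_h) {
  stopifnot(dt_h > 0)
  pconv <- 1 - exp(-log(2) / pool$plasma_halflife_h * dt_h)
  conv <- stats::rbinom(length(pool$pending), pool$pending, pconv)
  pool$pending <- pool$pending - conv
  pool$n_p <- pool$n_p + conv
  if (pool$k2_per_h > 0) {
    Ass <- pool$k1 / pool$volume_l * pool$n_p / pool$k2_per_h
    pool$A <- Ass + (pool$A - Ass) * exp(-pool$k2_per_h * dt_h)
  } else {
    pool$A <- pool$A + pool$k1 / pool$volume_l * pool$n_p * dt_h
  }
  pool
}

#' Run the antibody pool forward and record its trajectory
#'
#' @param pool an [antibody_pool()].
#' @param hours total time to simulate.
#' @param dt_h timestep (hours).
#' @return data.frame with one row per step: time, undifferentiated pending
#'   count, plasma count, total antibody concentration.
#' @export
antibody_run <- function(pool, hours, dt_h = 0.1) {
  steps <- ceiling(hours / dt_h)
  out <- data.frame(t = numeric(steps + 1), pending = NA_real_,
                    n_plasma = NA_real_, ab_total = NA_real_)
  rec <- function(i, t) {
    out$t[i] <<- t
    out$pending[i] <<- sum(pool$pending)
    out$n_plasma[i] <<- sum(pool$n_p)
    out$ab_total[i] <<- sum(pool$A)
  }
  rec(1, 0)
  for (s in seq_len(steps)) {
    pool <- antibody_step(pool, dt_h)
    rec(s + 1, s * dt_h)
  }
  attr(out, "pool") <- pool
  out
}

#' Equilibrium masked fraction of FDC antigen
#'
#' At equilibrium of the masking kinetics
#' `dC/dt = k_on G N A - k_off C`, the masked fraction of a site's antigen is
#' `C / (C + G) = N A / (N A + K_D)`.
#'
#' @param A antibody concentration (M); vectorized.
#' @param K_D dissociation constant (M).
#' @param N feedback scaling factor (number of synchronized GCs).
#' @export
mask_equilibrium <- function(A, K_D, N = 1) {
  N * A / (N * A + K_D)
}

#' Immune power of an antibody repertoire
#'
#' Efficiency statistic mimicking an ELISA: for a test antigen at
#' concentration `R`, each bin binds a fraction
#' `R_bound(i) = A(i) R / (K(i) + R)` and
#' `IP = sum_i R_bound(i) / R = sum_i A(i) / (K(i) + R)`.
#'
#' @param A per-bin antibody concentration (M), vector or matrix (rows =
#'   epitopes, columns = bins).
#' @param K_D per-bin dissociation constants (M).
#' @param R test antigen concentration (M).
#' @return the immune power (dimensionless).
#' @export
immune_power <- function(A, K_D, R = 1e-5) {
  if (is.matrix(A)) {
    if (ncol(A) != length(K_D)) stop("A columns must match K_D bins")
    sum(sweep(A, 2, K_D + R, "/"))
  } else {
    if (length(A) != length(K_D)) stop("A must match K_D bins")
    sum(A / (K_D + R))
  }
}

#' Fold change of immune power relative to a control run
#'
#' @param ip immune power of the mechanism run(s).
#' @param ip_control immune power of the corresponding control.
#' @export
ip_fold_change <- function(ip, ip_control) {
  if (any(ip_control <= 0)) stop("control immune power must be positive")
  ip / ip_control
}

#' Estimate the output-to-plasma differentiation half-life from a cohort
#'
#' Simulates a cohort of output cells through the antibody module with no
#' further GC input and fits the exponential decay of the undifferentiated
#' count by log-linear regression, returning the half-life and its standard
#' error.
#'
#' @param n_cells cohort size.
#' @param hours observation time.
#' @param dt_h timestep.
#' @param pool optional pre-configured [antibody_pool()].
#' @return list with `half_life_h`, `se_h`, and the fitted trajectory.
#' @export
plasma_halflife_fit <- function(n_cells = 10000, hours = 96, dt_h = 0.5,
                                pool = antibody_pool()) {
  pool <- add_output_cells(pool, rep(0.5, n_cells))
  tr <- antibody_run(pool, hours, dt_h)
  keep <- tr$pending > 0
  fit <- stats::lm(log(pending) ~ t, data = tr[keep, ])
  rate <- -unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  list(half_life_h = log(2) / rate,
       se_h = log(2) / rate^2 * se,
       trajectory = tr)
}
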