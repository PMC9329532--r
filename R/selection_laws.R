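# Closed-form laws: division program, Tfh signal intensity, mechanism
# schedules. All are simple Hill functions; they are exposed so that the
# agent engine's behavior can be checked against the analytic forms.

hill_frac <- function(x, K, n = 2) {
  out <- numeric(length(x))
  pos <- x > 0
  if (K <= 0) { out[pos] <- 1; return(out) }
  out[pos] <- x[pos]^n / (x[pos]^n + K^n)
  out
}

#' Division program of recycling B cells
#'
#' Number of divisions granted to a positively selected B cell as a Hill
#' function of its captured antigen (pMHC density, assumptions A1/A2) or its
#' integrated Tfh signal (A3/A4):
#' `n_div(x) = n_min + (n_max - n_min) * x^n / (x^n + K^n)`.
#' At `x = K` this evaluates to `(n_min + n_max) / 2`.
#'
#' @param x captured antigen (portions) or Tfh signal (hours); vectorized.
#' @param K half-effect constant, in the same units as `x`.
#' @param n_min,n_max minimum and maximum division numbers.
#' @param n Hill coefficient.
#' @return real-valued division number (rounding happens in the simulator).
#' @export
n_divisions <- function(x, K = 1, n_min = 1, n_max = 6, n = 2) {
  n_min + (n_max - n_min) * hill_frac(x, K, n)
}

#' Tfh signal intensity as a function of pMHC presentation
#'
#' Under the pMHC-dependent assumption sets (A2/A4) a polarized Tfh cell
#' delivers signal at intensity
#' `J(p) = J_min + (J_max - J_min) * p^n / (p^n + K_p^n)`;
#' under A1/A3 the intensity is constant (`J = 1`) and the signal measures
#' polarized contact time.
#'
#' @param p captured antigen (portions); vectorized.
#' @param J_min,J_max intensity range.
#' @param K_p half-effect pMHC density (portions).
#' @param n Hill coefficient.
#' @export
tfh_intensity <- function(p, J_min = 0, J_max = 3, K_p = 7.1, n = 2) {
  J_min + (J_max - J_min) * hill_frac(p, K_p, n)
}

#' Decaying Hill schedules (Tfh capacity, IC externalization)
#'
#' Time-dependent decay `f(t) = f0 * (1 - t^n / (t^n + K^n))`, used for the
#' maximal Tfh signaling intensity (half-decay time `K_T`) and for the
#' immune-complex externalization rate constant (half-decay time `K_ext`).
#' `K = Inf` disables the decay (control behavior).
#'
#' @param t time (hours); vectorized.
#' @param K half-decay time (hours).
#' @param f0 initial value.
#' @param n Hill coefficient.
#' @export
hill_decay_schedule <- function(t, K, f0 = 1, n = 2) {
  if (!is.finite(K)) return(rep(f0, length(t)))
  f0 * (1 - ifelse(t > 0, t^n / (t^n + K^n), 0))
}

#' @rdname hill_decay_schedule
#' @param T_max0 initial maximal signaling intensity.
#' @param K_T half-decay time of the Tfh signaling capacity (hours).
#' @export
tmax_schedule <- function(t, K_T, T_max0 = 1, n = 2) {
  hill_decay_schedule(t, K_T, T_max0, n)
}

#' @rdname hill_decay_schedule
#' @param k_ext0 initial externalization rate constant.
#' @param K_ext half-decay time of the externalization rate (hours).
#' @export
kext_schedule <- function(t, K_ext, k_ext0 = 1 / 36, n = 2) {
  hill_decay_schedule(t, K_ext, k_ext0, n)
}

#' Division-program constant under division-capacity exhaustion
#'
#' With mechanism M7 the half-effect constant of the division program grows
#' with the number of completed DZ-LZ cycles:
#' `K(N_cyc) = K_min + (K_max - K_min) * N^n / (N^n + K_K^n)`,
#' so that late-cycle cells earn fewer divisions for the same antigen or
#' signal. `K_K = Inf` keeps `K = K_min` (control).
#'
#' @param n_cyc completed DZ-LZ cycles; vectorized.
#' @param K_min,K_max range of the half-effect constant.
#' @param K_K cycle number at half-maximal increase.
#' @param n Hill coefficient.
#' @export
division_K <- function(n_cyc, K_min = 1, K_max = 25, K_K = 5, n = 2) {
  if (!is.finite(K_K)) return(rep(K_min, length(n_cyc)))
  K_min + (K_max - K_min) * hill_frac(n_cyc, K_K, n)
}

#' Terminal differentiation probability
#'
#' Probability that a Tfh-selected B cell differentiates to an output cell
#' instead of recycling. `diff_prob_hill()` is the antigen- or
#' Tfh-signal-dependent form `F = X^n / (X^n + K_F^n)` (mechanisms M6a/M6b);
#' `diff_prob_time()` is the time-dependent form `F = 1 - exp(-k t)` (M6c).
#' In controls `F = 0` and every selected cell recycles.
#'
#' @param x antigen (portions) or Tfh signal (hours); vectorized.
#' @param K_F half-maximal amount for differentiation.
#' @param n Hill coefficient.
#' @export
diff_prob_hill <- function(x, K_F, n = 2) {
  if (!is.finite(K_F)) return(rep(0, length(x)))
  hill_frac(x, K_F, n)
}

#' @rdname diff_prob_hill
#' @param t time (hours); vectorized.
#' @param k rate constant (per hour); `k = 0` gives `F = 0`.
#' @export
diff_prob_time <- function(t, k) {
  1 - exp(-k * t)
}

#' Surface fraction of FDC-held antigen under immune-complex cycling
#'
#' Integrates `dA_surf/dt = k_ext(t) (A_tot - A_surf) - k_int A_surf` for the
#' surface *fraction*, with the externalization rate following its Hill decay
#' schedule ([kext_schedule()]). Piecewise-exponential update; exact for
#' constant rates.
#'
#' @param times output times (hours, increasing, starting after 0).
#' @param phi0 initial surface fraction; default is the steady state of the
#'   initial rates.
#' @param k_int,k_ext0 cycling rate constants (per minute).
#' @param K_ext half-decay time of `k_ext` (hours); `Inf` = constant rates.
#' @return numeric vector of surface fractions at `times`.
#' @export
ic_surface_fraction <- function(times, phi0 = NULL, k_int = 1 / 21,
                                k_ext0 = 1 / 36, K_ext = Inf) {
  ki <- k_int * 60
  ke <- k_ext0 * 60
  if (is.null(phi0)) phi0 <- ke / (ke + ki)
  cpp_cycle_surface(phi0, ki, ke, K_ext, as.numeric(times))
}
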