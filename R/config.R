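# Run configuration: mechanisms, assumption sets, defaults, validation.

.mechanisms <- c("control", "M1", "M2", "M3", "M4", "M5", "M6a", "M6b", "M6c", "M7")
.assumptions <- c("A1", "A2", "A3", "A4")

# parameters that only make sense for one mechanism; passing them explicitly
# for a different mechanism is a configuration error
.mech_param_owner <- c(
  portions_per_encounter = "M1",
  ab_feedback_N = "M2",
  k_c = "M3", fdc_growth_rate = "M3", fdc_initial_um = "M3", fdc_switch_h = "M3",
  K_ext_h = "M4", k_int_per_min = "M4", k_ext0_per_min = "M4",
  K_T = "M5",
  K_F = "M6a|M6b", k_diff = "M6c",
  K_K = "M7", K_max = "M7"
)

# division-program half-effect constants per assumption set (baseline K = K_min;
# K_max only engages when division capacity is exhausted with DZ-LZ cycling, M7)
.division_K_defaults <- list(
  A1 = c(K_min = 1.0, K_max = 25.0),
  A2 = c(K_min = 1.0, K_max = 25.0),
  A3 = c(K_min = 0.5, K_max = 4.5),
  A4 = c(K_min = 0.0, K_max = 6.0)
)

#' Configure a germinal center simulation
#'
#' Builds a validated configuration object for [gc_simulate()]. Exactly one
#' shutdown mechanism is active per run; its control is the same run with the
#' mechanism's strength parameter at the neutral value (see Details).
#'
#' @param mechanism one of `"control"`, `"M1"` (antigen consumption by B
#'   cells), `"M2"` (antibody feedback / antigen masking), `"M3"` (FDC network
#'   contraction), `"M4"` (immune-complex cycling modulation), `"M5"`
#'   (decaying Tfh signaling capacity), `"M6a"`/`"M6b"`/`"M6c"` (terminal
#'   differentiation with antigen-, Tfh-signal- or time-dependent
#'   probability), `"M7"` (division-capacity exhaustion with DZ-LZ cycling).
#' @param assumption assumption set `"A1"`-`"A4"` coupling Tfh signal
#'   intensity and the division program to pMHC presentation:
#'   A1 = signal pMHC-independent, divisions pMHC-dependent;
#'   A2 = both pMHC-dependent; A3 = signal pMHC-independent, divisions
#'   Tfh-signal-dependent; A4 = signal pMHC-dependent, divisions
#'   Tfh-signal-dependent.
#' @param ... named overrides of the defaults listed under Details.
#'
#' @details
#' Mechanism strength parameters and their neutral (control) values:
#' `portions_per_encounter` (M1, portions removed from the FDC ledger per
#' successful encounter; 0 = no consumption), `ab_feedback_N` (M2, scaling of
#' the antibody concentration driving masking; 0 = no masking), `k_c` (M3, FDC
#' dendrite contraction rate in um/h after the growth phase; 0 = growth only),
#' `K_ext_h` (M4, half-decay time in hours of the externalization rate;
#' `Inf` = constant cycling rates), `K_T` (M5, half-decay time of the maximal
#' Tfh signaling intensity; `Inf` = constant), `K_F` (M6a/M6b, half-maximal
#' antigen/Tfh-signal amount for differentiation; `Inf` = no differentiation),
#' `k_diff` (M6c, rate of the time-dependent differentiation probability;
#' 0 = none), `K_K` (M7, DZ-LZ cycle number at half-maximal increase of the
#' division-program constant; `Inf` = constant K).
#'
#' Key base-model defaults (all overridable): lattice radius 160 um at 5 um
#' spacing, timestep 0.002 h, duration 21 days; 200 FDCs loaded with 3000
#' antigen portions each, 200 Tfh cells; founder influx 2 cells/h for 96 h
#' with 6 divisions each; mutation probability 0.5 per daughter; 72% of
#' antigen-carrying divisions asymmetric; antigen collection window 0.7 h with
#' at least 0.02 h between uptake events; Tfh contact 0.1 h, selection window
#' 3 h, signal threshold 0.5 h; division program n_min 1, n_max 6, Hill
#' coefficient 2; Tfh intensity J in [0, 3] with half-effect at 7.1 portions.
#'
#' @return an object of class `gc_config` (a named list).
#' @examples
#' cfg <- gc_config("M5", "A1", K_T = 600, duration_days = 7)
#' cfg$K_T
#' @export
gc_config <- function(mechanism = "control", assumption = "A1", ...) {
  mechanism <- match.arg(mechanism, .mechanisms)
  assumption <- match.arg(assumption, .assumptions)
  Kdef <- .division_K_defaults[[assumption]]

  defaults <- list(
    # geometry / time
    radius_um = 160, spacing_um = 5, dt_h = 0.002,
    duration_days = 21, out_every_h = 1,
    # shape space
    shape_lo = 0L, shape_hi = 9L, gamma = 2.8,
    epitopes = matrix(c(5L, 5L, 5L, 5L), nrow = 1),
    epitope_fractions = 1,
    founder_dmin = 2, founder_dmax = 5,
    # agents
    n_fdc = 200L, n_tfh = 200L, antigen_per_fdc = 3000,
    dendrite_um = 40,
    influx_rate = 2, influx_window_h = 96, founder_divisions = 6L,
    division_time_h = 6, division_jitter_h = 1,
    bcell_speed_um_min = 7.5, chemo_bias = 0.9, turn_prob = 0.3,
    mutation_prob = 0.5, asym_prob = 0.72,
    collect_window_h = 0.7, uptake_interval_h = 0.02,
    tfh_window_h = 3, tfh_threshold_h = 0.5, contact_duration_h = 0.1,
    rebind_delay_h = 0.1,
    # division program
    n_min = 1, n_max = 6, hill_n = 2,
    K_min = unname(Kdef["K_min"]), K_max = unname(Kdef["K_max"]),
    rounding = "stochastic",
    # Tfh signal model
    J_min = 0, J_max = 3, K_p = 7.1, T_max0 = 1,
    # mechanism parameters (neutral values = control behavior)
    portions_per_encounter = if (mechanism == "M1") 1 else 0,
    ab_feedback_N = if (mechanism == "M2") 300 else 0,
    k_c = if (mechanism == "M3") 0.166 else 0,
    fdc_growth_rate = 0.166, fdc_initial_um = 5, fdc_switch_h = 168,
    K_ext_h = if (mechanism == "M4") 150 else Inf,
    k_int_per_min = 1 / 21, k_ext0_per_min = 1 / 36,
    K_T = if (mechanism == "M5") 600 else Inf,
    K_F = if (mechanism == "M6a") 3 else if (mechanism == "M6b") 0.5 else Inf,
    k_diff = if (mechanism == "M6c") 0.003 else 0,
    K_K = if (mechanism == "M7") 5 else Inf,
    # antibody / immune power
    n_bins = 11L, k_on = 1e6, kd_lo_log10 = -5.5, kd_hi_log10 = -9.5,
    k1 = 3e-18, k2_per_h = log(2) / (14 * 24), volume_l = 0.01,
    plasma_halflife_h = 24, R_test = 1e-5,
    # bookkeeping
    max_cells = 200000L, record_events = FALSE, max_events = 5e6
  )

  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))

  # mechanism-specific parameters are rejected when their mechanism is inactive
  for (nm in intersect(names(dots), names(.mech_param_owner))) {
    owners <- strsplit(.mech_param_owner[[nm]], "|", fixed = TRUE)[[1]]
    if (!mechanism %in% owners)
      stop("parameter '", nm, "' belongs to mechanism ",
           .mech_param_owner[[nm]], " but mechanism is '", mechanism, "'")
  }

  cfg <- utils::modifyList(defaults, dots)
  cfg$mechanism <- mechanism
  cfg$assumption <- assumption
  validate_gc_config(cfg)
  structure(cfg, class = "gc_config")
}

#' Scaled-down configuration profile
#'
#' A reduced-geometry profile used for replicate suites: GC radius 90 um
#' with FDC and Tfh numbers scaled so that the FDC site coverage of the
#' light zone (~14%) and the Tfh density (hence the Tfh-limited selection
#' regime) of the full-size system are preserved at a fraction of the
#' computational cost; a coarser 1/150 h step that still divides the 0.02 h
#' minimum interval between antigen uptake events exactly; and the antibody
#' dilution volume scaled with the system (1.8 ml) so the feedback coupling
#' per unit of GC output is unchanged. All other parameters (influx,
#' windows, thresholds, mechanism laws) are unchanged. Any argument of
#' [gc_config()] can still be overridden through `...`.
#'
#' @inheritParams gc_config
#' @return a `gc_config` object.
#' @export
gc_scaled_config <- function(mechanism = "control", assumption = "A1", ...) {
  dots <- list(...)
  base <- list(radius_um = 90, n_fdc = 36L, n_tfh = 36L, dt_h = 1 / 150,
               volume_l = 0.0018)
  base <- base[!names(base) %in% names(dots)]
  do.call(gc_config, c(list(mechanism = mechanism, assumption = assumption),
                       base, dots))
}

validate_gc_config <- function(cfg) {
  stopifnot(cfg$spacing_um > 0, cfg$radius_um > cfg$spacing_um,
            cfg$dt_h > 0, cfg$duration_days > 0)
  if (cfg$uptake_interval_h < cfg$dt_h - 1e-12)
    stop("dt_h must resolve the minimum interval between uptake events")
  ep <- cfg$epitopes
  if (!is.matrix(ep) || ncol(ep) != 4)
    stop("epitopes must be a matrix with 4 columns (one row per epitope)")
  if (nrow(ep) != length(cfg$epitope_fractions) ||
      abs(sum(cfg$epitope_fractions) - 1) > 1e-9)
    stop("epitope_fractions must match the epitope rows and sum to 1")
  if (any(ep < cfg$shape_lo | ep > cfg$shape_hi))
    stop("epitopes outside shape-space bounds")
  rates <- c(cfg$fdc_growth_rate, cfg$k_c, cfg$k_int_per_min,
             cfg$k_ext0_per_min, cfg$k_diff, cfg$ab_feedback_N,
             cfg$portions_per_encounter)
  if (any(rates < 0)) stop("rate and strength parameters must be nonnegative")
  if (!cfg$rounding %in% c("stochastic", "nearest"))
    stop("rounding must be 'stochastic' or 'nearest'")
  if (cfg$founder_dmin > cfg$founder_dmax || cfg$founder_dmin < 0)
    stop("invalid founder distance band")
  invisible(cfg)
}

# flat numeric view consumed by the compiled engine
cfg_to_engine <- function(cfg, record_events = FALSE) {
  mech_id <- switch(cfg$mechanism,
                    control = 0L, M1 = 1L, M2 = 2L, M3 = 3L, M4 = 4L,
                    M5 = 5L, M6a = 6L, M6b = 6L, M6c = 6L, M7 = 7L)
  m6_mode <- switch(cfg$mechanism, M6a = 0L, M6b = 1L, M6c = 2L, 0L)
  list(
    radius_um = cfg$radius_um, spacing_um = cfg$spacing_um, dt_h = cfg$dt_h,
    duration_h = cfg$duration_days * 24, out_every_h = cfg$out_every_h,
    epitopes = matrix(as.integer(cfg$epitopes), nrow = nrow(cfg$epitopes)),
    epitope_fractions = as.numeric(cfg$epitope_fractions),
    shape_lo = as.integer(cfg$shape_lo), shape_hi = as.integer(cfg$shape_hi),
    gamma = cfg$gamma,
    founder_dmin = cfg$founder_dmin, founder_dmax = cfg$founder_dmax,
    n_fdc = as.integer(cfg$n_fdc), n_tfh = as.integer(cfg$n_tfh),
    antigen_per_fdc = cfg$antigen_per_fdc, dendrite_um = cfg$dendrite_um,
    influx_rate = cfg$influx_rate, influx_window_h = cfg$influx_window_h,
    founder_divisions = as.integer(cfg$founder_divisions),
    division_time_h = cfg$division_time_h,
    division_jitter_h = cfg$division_jitter_h,
    bcell_speed_um_min = cfg$bcell_speed_um_min, chemo_bias = cfg$chemo_bias,
    turn_prob = cfg$turn_prob,
    mutation_prob = cfg$mutation_prob, asym_prob = cfg$asym_prob,
    collect_window_h = cfg$collect_window_h,
    uptake_interval_h = cfg$uptake_interval_h,
    tfh_window_h = cfg$tfh_window_h, tfh_threshold_h = cfg$tfh_threshold_h,
    contact_duration_h = cfg$contact_duration_h,
    rebind_delay_h = cfg$rebind_delay_h,
    n_min = cfg$n_min, n_max = cfg$n_max, hill_n = cfg$hill_n,
    K_min = cfg$K_min, K_max = cfg$K_max,
    rounding_mode = if (cfg$rounding == "stochastic") 0L else 1L,
    J_min = cfg$J_min, J_max = cfg$J_max, K_p = cfg$K_p, T_max0 = cfg$T_max0,
    mech_id = mech_id, m6_mode = m6_mode,
    ndiv_on_p = cfg$assumption %in% c("A1", "A2"),
    J_of_p = cfg$assumption %in% c("A2", "A4"),
    portions_per_encounter = cfg$portions_per_encounter,
    ab_feedback_N = cfg$ab_feedback_N,
    k_c = cfg$k_c, fdc_growth_rate = cfg$fdc_growth_rate,
    fdc_initial_um = cfg$fdc_initial_um, fdc_switch_h = cfg$fdc_switch_h,
    K_ext_h = cfg$K_ext_h, k_int_per_min = cfg$k_int_per_min,
    k_ext0_per_min = cfg$k_ext0_per_min,
    K_T = cfg$K_T, K_F = cfg$K_F, k_diff = cfg$k_diff, K_K = cfg$K_K,
    n_bins = as.integer(cfg$n_bins), k_on = cfg$k_on,
    kd_lo_log10 = cfg$kd_lo_log10, kd_hi_log10 = cfg$kd_hi_log10,
    k1 = cfg$k1, k2_per_h = cfg$k2_per_h, volume_l = cfg$volume_l,
    plasma_halflife_h = cfg$plasma_halflife_h, R_test = cfg$R_test,
    max_cells = as.integer(cfg$max_cells),
    record_events = isTRUE(record_events) || isTRUE(cfg$record_events),
    max_events = cfg$max_events
  )
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config>\n")
  cat("  mechanism:  ", x$mechanism, "   assumption: ", x$assumption, "\n", sep = "")
  cat("  lattice:    radius ", x$radius_um, " um, spacing ", x$spacing_um,
      " um, dt ", x$dt_h, " h\n", sep = "")
  cat("  duration:   ", x$duration_days, " days\n", sep = "")
  cat("  agents:     ", x$n_fdc, " FDCs x ", x$antigen_per_fdc,
      " portions, ", x$n_tfh, " Tfh\n", sep = "")
  active <- switch(x$mechanism,
    M1 = paste0("portions_per_encounter = ", x$portions_per_encounter),
    M2 = paste0("ab_feedback_N = ", x$ab_feedback_N),
    M3 = paste0("k_c = ", x$k_c, " um/h"),
    M4 = paste0("K_ext_h = ", x$K_ext_h, " h"),
    M5 = paste0("K_T = ", x$K_T, " h"),
    M6a = paste0("K_F = ", x$K_F, " portions"),
    M6b = paste0("K_F = ", x$K_F, " signal-h"),
    M6c = paste0("k_diff = ", x$k_diff, " /h"),
    M7 = paste0("K_K = ", x$K_K, " cycles"),
    "none (control)")
  cat("  mechanism parameter: ", active, "\n", sep = "")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Flat key/value YAML mirroring the arguments of [gc_config()]; keys
#' `mechanism` and `assumption` select the run, all other keys are passed
#' through as overrides.
#'
#' @param path path to a YAML file.
#' @return a `gc_config` object.
#' @export
gc_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mech <- y$mechanism %||% "control"
  assum <- y$assumption %||% "A1"
  y$mechanism <- NULL
  y$assumption <- NULL
  if (!is.null(y$epitopes)) y$epitopes <- matrix(as.integer(unlist(y$epitopes)),
                                                 ncol = 4, byrow = TRUE)
  do.call(gc_config, c(list(mechanism = mech, assumption = assum), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
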