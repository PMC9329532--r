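# Small configurations used across tests. A "mini" GC: 70 um radius with a
# handful of FDCs/Tfh, a few days -- enough for every life-cycle event to
# occur while staying fast.

mini_config <- function(mechanism = "control", assumption = "A1", ...) {
  defaults <- list(radius_um = 70, n_fdc = 20L, n_tfh = 20L, dt_h = 0.005,
                   duration_days = 6, volume_l = 0.001)
  dots <- list(...)
  defaults <- defaults[!names(defaults) %in% names(dots)]
  do.call(gc_config, c(list(mechanism = mechanism, assumption = assumption),
                       defaults, dots))
}

# brute-force enumeration of integer lattice points within a sphere,
# independent of the engine's implementation
brute_sphere_count <- function(radius_um, spacing_um) {
  R <- floor(radius_um / spacing_um + 1e-9)
  g <- expand.grid(x = -R:R, y = -R:R, z = -R:R)
  sum(g$x^2 + g$y^2 + g$z^2 <= R^2)
}
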