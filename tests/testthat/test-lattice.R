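# Spherical lattice geometry and zone partition.

test_that("site count matches brute-force sphere enumeration", {
  for (r in c(10, 35, 90)) {
    info <- lattice_info(radius_um = r, spacing_um = 5)
    expect_identical(info$n_sites, brute_sphere_count(r, 5))
  }
})

test_that("DZ and LZ partition the sphere", {
  info <- lattice_info(90, 5)
  expect_identical(info$n_dz + info$n_lz, info$n_sites)
  expect_gt(info$n_dz, 0)
  expect_gt(info$n_lz, 0)
  expect_error(lattice_info(3, 5))
})

test_that("FDC somata and Tfh cells are placed in the light zone", {
  run <- gc_simulate(mini_config(duration_days = 1 / 24), seed = 5)
  expect_identical(run$lattice$n_fdc, 20L)
  expect_identical(run$lattice$n_tfh, 20L)
  expect_identical(run$lattice$n_fdc_somas_lz, run$lattice$n_fdc)
  expect_identical(run$lattice$n_tfh_lz, run$lattice$n_tfh)
})
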