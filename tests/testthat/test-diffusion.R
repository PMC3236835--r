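kB <- 1.380649e-23
N_A <- 6.02214076e23

test_that("classical Stokes-Einstein values and scaling", {
  D30 <- classical_stokes_einstein(30e-9)
  expect_equal(D30, kB * 298.15 / (6 * pi * 0.89e-3 * 30e-9))
  expect_equal(D30, 8.18e-12, tolerance = 1e-3)
  expect_equal(classical_stokes_einstein(80e-9), 3.07e-12, tolerance = 1e-3)
  expect_equal(classical_stokes_einstein(60e-9), D30 / 2)
  expect_error(classical_stokes_einstein(-1e-9), "positive")
})

test_that("sedimentation coefficient: buoyancy, linearity, Svedberg link", {
  expect_equal(sedimentation_coefficient(1e5, 1.25, 0.8, 0.89e-3, 30e-9), 0)
  s1 <- sedimentation_coefficient(1e5, 0.73, 1.0, 0.89e-3, 30e-9)
  expect_equal(s1, (1e5 * 1e-3 / N_A) * (1 - 0.73) /
                 (6 * pi * 0.89e-3 * 30e-9))
  expect_equal(sedimentation_coefficient(2e5, 0.73, 1.0, 0.89e-3, 30e-9),
               2 * s1)
  # s and D share the drag: s = D * m (1 - vbar rho) / (kB T)
  D <- classical_stokes_einstein(30e-9)
  expect_equal(s1, D * (1e5 * 1e-3 / N_A) * (1 - 0.73) / (kB * 298.15))
})

test_that("concentrations convert to volume fractions via N_A C V", {
  geoms <- build_species_geometries(1, base_protofibril())
  zero <- concentrations_to_volume_fractions(0, geoms)
  expect_equal(zero$phi0, 1)
  comp <- concentrations_to_volume_fractions(5, geoms, unit = "uM")
  V1 <- spheroid_volume(base_protofibril())
  expect_equal(comp$phi, N_A * 5e-3 * V1)
  expect_equal(comp$phi, 1.92e-2, tolerance = 1e-2)
  expect_equal(comp$phi0, 1 - comp$phi)
  # solute-normalized mode tags the composition
  sn <- concentrations_to_volume_fractions(5, geoms, "solute_normalized",
                                           unit = "uM")
  expect_equal(sn$normalization, "solute_normalized")
  # unphysical concentrations are rejected
  expect_error(concentrations_to_volume_fractions(60, geoms), "> 1")
})

test_that("diffusion bounds recover dilute-limit drags and order correctly", {
  geoms <- build_species_geometries(1, base_protofibril())
  dilute <- concentrations_to_volume_fractions(1e-9, geoms, unit = "uM")
  b <- effective_diffusion_bounds(dilute, geoms)
  pf <- base_protofibril()
  expect_equal(b$k_upper,
               kB * 298.15 / spheroid_drag_parallel(pf, 0.89e-3)$value,
               tolerance = 1e-6)
  expect_equal(b$k_lower,
               kB * 298.15 / spheroid_drag_perpendicular(pf, 0.89e-3)$value,
               tolerance = 1e-6)
  expect_equal(b$k_upper, 6.23e-12, tolerance = 1e-2)
  expect_equal(b$k_lower, 3.73e-12, tolerance = 1e-2)
})

test_that("a spherical species reports the classical value as both bounds", {
  sph_geom <- list(structure(
    list(n = 1, shape = sphere_shape(30e-9),
         particle_volume = 4 / 3 * pi * (30e-9)^3, monomer_count = 1600L),
    class = "species_geometry"))
  comp <- mixture_composition(0, phi0 = 1)
  b <- effective_diffusion_bounds(comp, sph_geom)
  expect_equal(b$k_lower, classical_stokes_einstein(30e-9))
  expect_identical(b$k_lower, b$k_upper)
})

test_that("k_lower <= k_upper and both shrink with viscosity and size", {
  geoms <- build_species_geometries(5, base_protofibril())
  set.seed(31)
  for (k in 1:10) {
    conc <- runif(5, 0, 1)  # uM
    comp <- concentrations_to_volume_fractions(conc, geoms, unit = "uM")
    b <- effective_diffusion_bounds(comp, geoms)
    expect_true(all(b$k_lower <= b$k_upper))
    expect_true(all(b$k_lower > 0))
    # larger laterally-associated species diffuse more slowly, both bounds
    expect_true(all(diff(b$k_lower) < 0))
    expect_true(all(diff(b$k_upper) < 0))
  }
  # higher effective viscosity lowers every bound
  lo <- effective_diffusion_bounds(
    concentrations_to_volume_fractions(c(1, 0, 0, 0, 0), geoms,
                                       unit = "uM"), geoms)
  hi <- effective_diffusion_bounds(
    concentrations_to_volume_fractions(c(5, 1, 1, 1, 1), geoms,
                                       unit = "uM"), geoms)
  expect_true(hi$eta_e[1] > lo$eta_e[1])
  expect_true(all(hi$k_upper < lo$k_upper))
})

test_that("one-species limit recovers the classical law and its expansion", {
  a <- 30e-9
  at_zero <- one_species_limit(0, a)
  expect_identical(at_zero$full, classical_stokes_einstein(a))
  expect_identical(at_zero$first_order, classical_stokes_einstein(a))
  # O(eps) expansion agrees with the closed form at eps = 1e-3
  eps <- 1e-3
  phi <- eps / (1 + eps)   # phi/phi0 = eps with phi0 + phi = 1
  res <- one_species_limit(phi, a)
  expect_equal(res$eps, eps)
  expect_lt(abs(res$full - res$first_order) / res$full, 1e-5)
  # decreasing in phi
  d <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(p) {
    one_species_limit(p, a)$full
  }, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_error(one_species_limit(0.6, a), "singular")
})

test_that("one-species limit agrees with the n=1 solute-normalized pipeline", {
  a <- 30e-9
  phi <- 0.0192
  comp <- mixture_composition(phi, normalization = "solute_normalized")
  eta_e <- mixture_effective_viscosity(comp)
  expect_equal(kB * 298.15 / (6 * pi * eta_e * a),
               one_species_limit(phi, a)$full)
})
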