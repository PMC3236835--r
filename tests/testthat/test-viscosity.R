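test_that("Quemada viscosity: closed form, monotonicity, divergence", {
  expect_equal(quemada_viscosity(0, eta0 = 1), 1)
  expect_equal(quemada_viscosity(0.3, eta0 = 1, phi_m = 0.6), 4)
  expect_error(quemada_viscosity(0.6, phi_m = 0.6), "singular")
  expect_error(quemada_viscosity(-0.1), "nonnegative")
  grid <- seq(0, 0.59, by = 0.01)
  eta <- quemada_viscosity(grid, eta0 = 1, phi_m = 0.6)
  expect_true(all(diff(eta) > 0))            # strictly increasing
  expect_true(all(diff(diff(eta)) > 0))      # convex
  expect_gt(quemada_viscosity(0.999 * 0.6, eta0 = 1, phi_m = 0.6), 1e3)
})

test_that("mixture composition validates fractions and normalization", {
  comp <- mixture_composition(c(0.02, 0.01))
  expect_equal(comp$phi0, 0.97)
  expect_equal(comp$normalization, "absolute")
  expect_error(mixture_composition(c(0.5, 0.6)), "sum to 1")
  expect_error(mixture_composition(c(-0.1), phi0 = 1.1), "nonnegative")
})

test_that("relative solute fractions follow the cyclic chain", {
  # single species: nothing to exclude
  one <- mixture_composition(0.02, phi0 = 0.98)
  expect_equal(unname(relative_solute_fractions(one, 1)), 0.02)
  # two equal species are symmetric under the cyclic rule
  two <- mixture_composition(c(0.03, 0.03))
  expect_equal(unname(relative_solute_fractions(two, 1)),
               unname(relative_solute_fractions(two, 2)))
  # three species: compare with the directly enumerated nested fractions
  phi <- c(0.04, 0.02, 0.01)
  phi0 <- 1 - sum(phi)
  comp <- mixture_composition(phi)
  expect_equal(
    unname(relative_solute_fractions(comp, 1)),
    c(phi[1] / (phi0 + phi[1] + phi[2] + phi[3]),
      phi[2] / (phi0 + phi[2] + phi[3]),
      phi[3] / (phi0 + phi[3])))
  expect_equal(
    unname(relative_solute_fractions(comp, 2)),
    c(phi[2] / (phi0 + phi[2] + phi[3] + phi[1]),
      phi[3] / (phi0 + phi[3] + phi[1]),
      phi[1] / (phi0 + phi[1])))
  expect_equal(names(relative_solute_fractions(comp, 3)),
               c("3", "1", "2"))
  expect_error(relative_solute_fractions(comp, 4), "integer in 1..3")
})

test_that("cyclic mixture viscosity: limits, symmetry, averaging", {
  eta0 <- 0.89e-3
  # zero solute -> pure solvent, both modes
  expect_equal(mixture_effective_viscosity(mixture_composition(0),
                                           eta0 = eta0), eta0)
  expect_equal(mixture_effective_viscosity(
    mixture_composition(numeric(0), phi0 = 1), eta0 = eta0), eta0)
  # one species, absolute weights: frozen from the nested closed form
  one <- mixture_composition(0.0192)
  expect_equal(mixture_effective_viscosity(one, eta0 = eta0),
               0.9808 * eta0 + 0.0192 * eta0 * (1 - 0.0192 / 0.6)^(-2))
  expect_equal(mixture_effective_viscosity(one, eta0 = eta0),
               8.911e-4, tolerance = 1e-4)
  # two-species label swap leaves eta_e unchanged
  ab <- mixture_composition(c(0.05, 0.01))
  ba <- mixture_composition(c(0.01, 0.05))
  expect_equal(mixture_effective_viscosity(ab), mixture_effective_viscosity(ba))
  # always >= eta0, equality iff no solute
  set.seed(7)
  for (k in 1:10) {
    phi <- runif(3, 0, 0.05)
    comp <- mixture_composition(phi)
    expect_gt(mixture_effective_viscosity(comp, eta0 = eta0), eta0)
  }
  # weighted-average property: eta_e between min and max component
  phi <- c(0.06, 0.03, 0.01)
  comp <- mixture_composition(phi)
  components <- c(eta0, vapply(1:3, function(j) {
    rel <- relative_solute_fractions(comp, j)
    eta0 * prod((1 - rel / 0.6)^(-2))
  }, numeric(1)))
  eta_e <- mixture_effective_viscosity(comp, eta0 = eta0)
  expect_gte(eta_e, min(components))
  expect_lte(eta_e, max(components))
  # singularity surfaces as an error
  expect_error(
    mixture_effective_viscosity(mixture_composition(0.61), eta0 = eta0),
    "singular")
})

test_that("solute-normalized n=1 reduction matches the one-species closed form", {
  eta0 <- 0.89e-3
  for (phi in c(1e-4, 0.0192, 0.2, 0.5)) {
    comp <- mixture_composition(phi, normalization = "solute_normalized")
    expect_identical(mixture_effective_viscosity(comp, eta0 = eta0),
                     eta0 * (1 - phi / 0.6)^(-2))
  }
})

test_that("sphere-rod viscosity: limits, branches, applicability", {
  rod <- rod_shape(600e-9, 4.5e-9)
  sph <- sphere_shape(2e-9)       # semi-length/radius = 150 > 20
  eta0 <- 0.89e-3
  expect_equal(as.numeric(sphere_rod_effective_viscosity(0, 0, rod, sph,
                                                         eta0 = eta0)),
               eta0)
  # no rods: pure Thomas sphere factor
  phi_s <- 0.05
  phi_hat <- phi_s / (1 - phi_s + phi_s)
  thomas <- 1 + 2.5 * phi_hat + 10.05 * phi_hat^2 +
    0.00273 * (exp(16.6 * phi_hat) - 1)
  expect_equal(as.numeric(sphere_rod_effective_viscosity(0, phi_s, rod, sph,
                                                         eta0 = eta0)),
               thomas * eta0)
  # branch selection: dilute at the 0.125 boundary, continuous across it
  lo <- sphere_rod_effective_viscosity(0.125, 0.01, rod, sph, eta0 = eta0)
  hi <- sphere_rod_effective_viscosity(0.125 + 1e-9, 0.01, rod, sph,
                                       eta0 = eta0)
  expect_equal(attr(lo, "branch"), "dilute")
  expect_equal(attr(hi, "branch"), "semidilute")
  expect_equal(as.numeric(lo), as.numeric(hi), tolerance = 1e-6)
  # increasing in rod fraction across both branches
  vals <- vapply(c(0.01, 0.05, 0.1, 0.125, 0.2, 0.3), function(p) {
    as.numeric(sphere_rod_effective_viscosity(p, 0.01, rod, sph,
                                              eta0 = eta0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # aspect-ratio applicability guard
  expect_error(
    sphere_rod_effective_viscosity(0.01, 0.01, rod, sphere_shape(50e-9)),
    "> 20")
})

test_that("sphere-rod diffusion uses the rod shape factor and branch", {
  rod <- rod_shape(600e-9, 4.5e-9)
  sph <- sphere_shape(2e-9)
  d_par <- sphere_rod_diffusion(0.01, 0.01, rod, sph, "parallel")
  d_perp <- sphere_rod_diffusion(0.01, 0.01, rod, sph, "perpendicular")
  expect_equal(as.numeric(d_par) / as.numeric(d_perp), 2)
  expect_equal(attr(d_par, "branch"), "dilute")
  expect_equal(attr(sphere_rod_diffusion(0.3, 0.01, rod, sph), "branch"),
               "semidilute")
})
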