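# Shared fixtures and independent oracles for the test suite.

# Base protofibril envelope used throughout: semi-axes 300 nm x 2.25 nm.
base_protofibril <- function() spheroid_shape(300e-9, 2.25e-9)

# Cache the case-study simulations so several test files can share them.
.case_cache <- new.env(parent = emptyenv())
case_sim <- function(n_species, init_conc_uM = 5) {
  key <- sprintf("n%d_c%g", n_species, init_conc_uM)
  if (is.null(.case_cache[[key]])) {
    .case_cache[[key]] <- run_case(
      simulation_config(n_species = n_species, init_conc_uM = init_conc_uM))
  }
  .case_cache[[key]]
}

# Independent drag oracle: Oberbeck's elliptic-integral friction for a
# triaxial ellipsoid (semi-axes a1 along the motion, a2, a3), evaluated by
# numerical quadrature. Completely separate route from the closed forms
# under test.
oberbeck_drag <- function(a1, a2, a3, eta) {
  # work in nm to keep the quadrature well-scaled; drag is linear in size
  s <- 1e9
  A1 <- a1 * s; A2 <- a2 * s; A3 <- a3 * s
  delta <- function(t) sqrt((A1^2 + t) * (A2^2 + t) * (A3^2 + t))
  chi <- stats::integrate(function(t) 1 / delta(t), 0, Inf,
                          rel.tol = 1e-11)$value
  alpha1 <- stats::integrate(function(t) 1 / ((A1^2 + t) * delta(t)), 0,
                             Inf, rel.tol = 1e-11)$value
  16 * pi * eta / ((chi + A1^2 * alpha1) * s)
}

# Analytic 2-species equilibrium of F1 + F1 <-> F2 at total monomer mass M
# (mM of 1600-mer equivalents): k_plus x^2 = k_minus y with x + 2y = M.
equilibrium_2species <- function(M, k_plus, k_minus) {
  x <- (-k_minus + sqrt(k_minus^2 + 8 * k_plus * k_minus * M)) /
    (4 * k_plus)
  c(F1 = x, F2 = (M - x) / 2)
}
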