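# CODATA constants
.kB <- 1.380649e-23      # Boltzmann constant, J/K
.N_A <- 6.02214076e23    # Avogadro number, mol^-1

#' Classical Stokes-Einstein diffusion coefficient
#'
#' `D = k_B T / (6 pi eta0 a)` for a rigid sphere of radius `a` in a solvent
#' of constant viscosity `eta0`. This is the relation DLS instruments invert
#' to report hydrodynamic radii; the rest of the package replaces both the
#' sphere drag (orientation-resolved spheroids) and the constant solvent
#' viscosity (concentration-dependent effective viscosity).
#'
#' @param a Hydrodynamic radius (m).
#' @param eta0 Solvent viscosity (Pa s).
#' @param temperature Absolute temperature (K); default 298.15 (room
#'   temperature).
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' classical_stokes_einstein(30e-9)  # ~8.2e-12 m^2/s
#' @export
classical_stokes_einstein <- function(a, eta0 = 0.89e-3,
                                      temperature = 298.15) {
  .check_positive(a = a, eta0 = eta0, temperature = temperature)
  .kB * temperature / (6 * pi * eta0 * a)
}

#' Sedimentation coefficient of a spherical solute
#'
#' Rate of migration per unit centrifugal field measured by analytical
#' ultracentrifugation: `s = M_A (1 - vbar rho) / (N_A 6 pi eta a)`, for a
#' solute of molar mass `M_A`, partial specific volume `vbar`, in a buffer
#' of density `rho` and viscosity `eta`.
#'
#' @param mass_g_mol Molar mass `M_A` (g/mol).
#' @param vbar_ml_g Partial specific volume (mL/g).
#' @param rho_g_ml Buffer density (g/mL).
#' @param eta Buffer viscosity (Pa s).
#' @param a Particle radius (m).
#' @return Sedimentation coefficient (s); zero at neutral buoyancy
#'   (`vbar * rho = 1`).
#' @export
sedimentation_coefficient <- function(mass_g_mol, vbar_ml_g, rho_g_ml,
                                      eta, a) {
  .check_positive(mass_g_mol = mass_g_mol, vbar_ml_g = vbar_ml_g,
                  rho_g_ml = rho_g_ml, eta = eta, a = a)
  mass_kg <- mass_g_mol * 1e-3 / .N_A   # mass per particle, kg
  mass_kg * (1 - vbar_ml_g * rho_g_ml) / (6 * pi * eta * a)
}

#' Convert species concentrations to a suspension composition
#'
#' Volume fraction of species i at number concentration `C_i`:
#' `phi_i = N_A C_i V_i` with `C_i` in mol/m^3 (numerically equal to mM) and
#' `V_i` the per-particle volume from the species geometry. The solvent
#' takes up the remainder, `phi0 = 1 - sum(phi)`.
#'
#' @param state Species concentrations (vector, species `1..n`), in mM
#'   unless `unit = "uM"`.
#' @param geometries List of `species_geometry` from
#'   [build_species_geometries()], same length as `state`.
#' @param normalization Passed to [mixture_composition()]: `"absolute"` or
#'   `"solute_normalized"`.
#' @param unit `"mM"` (default) or `"uM"`.
#' @return A [mixture_composition()]. Errors if the solute fractions exceed
#'   1.
#' @examples
#' geoms <- build_species_geometries(1, spheroid_shape(300e-9, 2.25e-9))
#' concentrations_to_volume_fractions(5, geoms, unit = "uM")  # phi1 ~ 0.0192
#' @export
concentrations_to_volume_fractions <- function(state, geometries,
                                               normalization = c("absolute",
                                                                 "solute_normalized"),
                                               unit = c("mM", "uM")) {
  normalization <- match.arg(normalization)
  unit <- match.arg(unit)
  stopifnot(is.numeric(state), is.list(geometries),
            length(state) == length(geometries))
  if (any(state < 0)) stop("concentrations must be nonnegative",
                           call. = FALSE)
  if (unit == "uM") state <- state / 1000
  volumes <- vapply(geometries, function(g) g$particle_volume, numeric(1))
  phi <- .N_A * state * volumes   # mM == mol/m^3
  if (sum(phi) > 1) {
    stop(sprintf("solute volume fractions sum to %.4g > 1: concentrations are unphysical for these geometries",
                 sum(phi)), call. = FALSE)
  }
  mixture_composition(phi, phi0 = 1 - sum(phi), normalization = normalization)
}

#' Effective diffusion bounds under the modified Stokes-Einstein relation
#'
#' For each species, replaces the solvent viscosity in the Stokes-Einstein
#' relation with the suspension's effective viscosity
#' ([mixture_effective_viscosity()]) and the sphere drag with the species'
#' orientation-resolved drag. A spheroidal species has no single diffusion
#' coefficient - its drag depends on its orientation - so the model reports
#' the bracket: `k_upper = k_B T / f_par` (motion along the major axis,
#' least drag) and `k_lower = k_B T / f_perp`. Spherical species are
#' isotropic and report one value as both bounds; at vanishing solute
#' fraction that value is exactly the classical Stokes-Einstein
#' coefficient.
#'
#' @param composition A [mixture_composition()] for the current state.
#' @param geometries List of `species_geometry`, one per species.
#' @param eta0 Solvent viscosity (Pa s).
#' @param phi_m Maximum packing fraction.
#' @param temperature Absolute temperature (K).
#' @return A data.frame with one row per species: `species` (multiplicity
#'   n), `k_lower`, `k_upper` (m^2/s), and `eta_e` (Pa s, identical across
#'   rows).
#' @export
effective_diffusion_bounds <- function(composition, geometries,
                                       eta0 = 0.89e-3, phi_m = 0.6,
                                       temperature = 298.15) {
  stopifnot(inherits(composition, "mixture_composition"),
            length(composition$phi) == length(geometries))
  .check_positive(temperature = temperature)
  eta_e <- mixture_effective_viscosity(composition, eta0 = eta0,
                                       phi_m = phi_m)
  kT <- .kB * temperature
  rows <- lapply(geometries, function(g) {
    shp <- g$shape
    if (inherits(shp, "sphere_shape")) {
      d_iso <- kT / sphere_drag(shp$a, eta_e)$value
      c(k_lower = d_iso, k_upper = d_iso)
    } else {
      c(k_lower = kT / spheroid_drag_perpendicular(shp, eta_e)$value,
        k_upper = kT / spheroid_drag_parallel(shp, eta_e)$value)
    }
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(species = vapply(geometries, function(g) g$n, numeric(1)),
               out)
  out$eta_e <- eta_e
  out
}

#' One-species reduction of the modified Stokes-Einstein model
#'
#' For a single spherical species at solute fraction `phi` in solvent
#' fraction `phi0` (with `phi0 + phi = 1`), discounting the fluid in the
#' effective-viscosity average leaves `eta_e = eta0 (1 - phi/phi_m)^(-2)`,
#' so the modified diffusion coefficient is
#' \deqn{D = \frac{k_B T}{6\pi\eta_0 a}\,\left(1 - \phi/\phi_m\right)^2.}
#' Writing `eps = phi/phi0 << 1`, the first-order expansion is
#' `D ~= D_SE (1 - 2 phi / phi_m)`, accurate to `O(eps^2)`; both forms
#' recover the classical relation exactly at `phi = 0`.
#'
#' @param phi Solute volume fraction, `0 <= phi < phi_m`.
#' @param a Particle radius (m).
#' @param phi0 Solvent volume fraction (default `1 - phi`).
#' @param eta0 Solvent viscosity (Pa s).
#' @param phi_m Maximum packing fraction.
#' @param temperature Absolute temperature (K).
#' @return List with `full` (the closed form) and `first_order` (the small-
#'   `eps` expansion), both in m^2/s, plus `eps = phi/phi0`.
#' @export
one_species_limit <- function(phi, a, phi0 = 1 - phi, eta0 = 0.89e-3,
                              phi_m = 0.6, temperature = 298.15) {
  stopifnot(is.numeric(phi), length(phi) == 1L)
  if (phi < 0) stop("'phi' must be nonnegative", call. = FALSE)
  if (phi >= phi_m) {
    stop(sprintf("phi = %.4g reaches phi_m = %.4g: viscosity is singular",
                 phi, phi_m), call. = FALSE)
  }
  if (phi0 <= 0) stop("'phi0' must be positive", call. = FALSE)
  d_se <- classical_stokes_einstein(a, eta0 = eta0,
                                    temperature = temperature)
  list(full = d_se * (1 - phi / phi_m)^2,
       first_order = d_se * (1 - 2 * phi / phi_m),
       eps = phi / phi0)
}

#' Diffusion coefficient in the sphere-rod empirical model
#'
#' Companion to [sphere_rod_effective_viscosity()]: the rod's diffusion
#' coefficient `D = k_B T / (S eta_e L)`, where `S` is the orientation-
#' dependent slender-rod shape factor ([rod_shape_factor()]) and `eta_e`
#' the bidisperse effective viscosity, whose dilute/semidilute rod branch
#' is selected at `phi_r = 0.125`.
#'
#' @inheritParams sphere_rod_effective_viscosity
#' @param orientation `"parallel"` or `"perpendicular"` rod motion.
#' @param temperature Absolute temperature (K).
#' @return Diffusion coefficient (m^2/s), with attribute `branch` from the
#'   viscosity model.
#' @export
sphere_rod_diffusion <- function(phi_r, phi_s, rod, sphere,
                                 orientation = c("parallel",
                                                 "perpendicular"),
                                 eta0 = 0.89e-3, phi_m = 0.6,
                                 temperature = 298.15) {
  orientation <- match.arg(orientation)
  .check_positive(temperature = temperature)
  eta_e <- sphere_rod_effective_viscosity(phi_r, phi_s, rod, sphere,
                                          eta0 = eta0, phi_m = phi_m)
  S <- rod_shape_factor(rod, orientation)
  structure(.kB * temperature / (S * as.numeric(eta_e) * rod$L),
            branch = attr(eta_e, "branch"))
}
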