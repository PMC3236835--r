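#' Quemada viscosity of a hard-particle suspension
#'
#' Empirical viscosity of a suspension of hard spheres or aggregate-like
#' structural units at volume fraction `phi`:
#' \deqn{\eta(\phi) = \eta_0 \,(1 - \phi/\phi_m)^{-2},}
#' where `phi_m` is the maximum packing fraction at which the viscosity
#' diverges and flow ceases. Literature estimates place `phi_m` between
#' 0.58 and 0.69; the default is the mid-range value 0.6.
#'
#' @param phi Particle volume fraction, `0 <= phi < phi_m`.
#' @param eta0 Viscosity of the background medium (Pa s); default is water,
#'   0.89e-3 Pa s.
#' @param phi_m Maximum packing fraction, in `(0, 1]`; default 0.6.
#' @return Suspension viscosity (Pa s); strictly increasing and convex in
#'   `phi`.
#' @examples
#' quemada_viscosity(0.3, eta0 = 1, phi_m = 0.6)  # (1 - 0.5)^-2 = 4
#' @export
quemada_viscosity <- function(phi, eta0 = 0.89e-3, phi_m = 0.6) {
  .check_positive(eta0 = eta0, phi_m = phi_m)
  if (phi_m > 1) stop("'phi_m' must be in (0, 1]", call. = FALSE)
  stopifnot(is.numeric(phi))
  if (any(phi < 0)) stop("volume fraction 'phi' must be nonnegative",
                         call. = FALSE)
  if (any(phi >= phi_m)) {
    stop(sprintf(
      "volume fraction %.4g reaches the packing fraction phi_m = %.4g: viscosity is singular",
      max(phi), phi_m), call. = FALSE)
  }
  eta0 * (1 - phi / phi_m)^(-2)
}

#' Composition of a multi-species suspension
#'
#' A suspension of `n` solute species in a solvent, described by volume
#' fractions. `phi` holds the absolute per-species solute fractions
#' `V_i / V_total` and `phi0 = 1 - sum(phi)` the solvent fraction. The
#' `normalization` mode controls how [mixture_effective_viscosity()] weights
#' the components:
#' \describe{
#'   \item{`"absolute"`}{weights are the absolute fractions
#'     (`phi0` for the solvent, `phi_j` for each solute), which sum to 1.}
#'   \item{`"solute_normalized"`}{the fluid is discounted: weights are the
#'     solute fractions rescaled to sum to 1 (`psi_j = phi_j / sum(phi)`),
#'     reflecting that only the solute species diffuse. This is the
#'     convention used in the case studies.}
#' }
#' In both modes the component viscosities themselves are computed from the
#' physical (absolute) fractions; normalization only changes the averaging
#' weights.
#'
#' @param phi Numeric vector of per-species solute volume fractions (>= 0).
#' @param phi0 Solvent volume fraction; default `1 - sum(phi)`.
#' @param normalization `"absolute"` or `"solute_normalized"`.
#' @return A `mixture_composition` object.
#' @export
mixture_composition <- function(phi, phi0 = 1 - sum(phi),
                                normalization = c("absolute",
                                                  "solute_normalized")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(phi), is.numeric(phi0), length(phi0) == 1L)
  if (any(phi < 0)) {
    stop("volume fractions must be nonnegative", call. = FALSE)
  }
  total <- phi0 + sum(phi)
  if (phi0 < 0 || abs(total - 1) > 1e-8) {
    stop(sprintf(
      "volume fractions must sum to 1 (solvent %.8g + solutes %.8g)",
      phi0, sum(phi)), call. = FALSE)
  }
  structure(list(phi0 = phi0, phi = as.numeric(phi),
                 normalization = normalization),
            class = "mixture_composition")
}

#' @export
print.mixture_composition <- function(x, ...) {
  cat(sprintf("<mixture_composition> %d species, phi0 = %.4g, phi = [%s] (%s)\n",
              length(x$phi), x$phi0,
              paste(format(x$phi, digits = 4), collapse = ", "),
              x$normalization))
  invisible(x)
}

#' Relative solute fractions along the cyclic mixing chain
#'
#' The effective-viscosity recipe treats the suspension seen by solute `j`
#' as built up in layers: `j` floats in a medium made of the solvent plus
#' all other solutes, which is itself a suspension of solute `j+1` in the
#' solvent plus the remaining solutes, and so on through the cyclic order
#' `j, j+1, ..., n, 1, ..., j-1`. The fraction of the species at each layer
#' is taken relative to the sub-suspension that contains it (the solvent
#' plus that species and everything deeper in the chain); the outermost
#' layer's fraction is therefore the plain absolute fraction, with nothing
#' excluded.
#'
#' @param composition A [mixture_composition()].
#' @param j Solute index, `1 <= j <= n`.
#' @return Named numeric vector of relative fractions in chain order
#'   (outermost first); names are the species indices.
#' @examples
#' comp <- mixture_composition(c(0.02), phi0 = 0.98)
#' relative_solute_fractions(comp, 1)  # 0.02: nothing to exclude
#' @export
relative_solute_fractions <- function(composition, j) {
  stopifnot(inherits(composition, "mixture_composition"))
  n <- length(composition$phi)
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > n || j != round(j)) {
    stop(sprintf("solute index 'j' must be an integer in 1..%d", n),
         call. = FALSE)
  }
  ord <- ((j - 1 + seq_len(n) - 1) %% n) + 1  # j, j+1, ..., n, 1, ..., j-1
  phi <- composition$phi[ord]
  # denominator at layer p: solvent + species at layers p..n (inner + self)
  denom <- composition$phi0 + rev(cumsum(rev(phi)))
  out <- ifelse(denom > 0, phi / denom, 0)
  names(out) <- as.character(ord)
  out
}

# Component viscosity eta_j: nested Quemada cascade along the chain for j.
.component_viscosity <- function(composition, j, eta0, phi_m) {
  rel <- relative_solute_fractions(composition, j)
  if (any(rel >= phi_m)) {
    stop(sprintf(
      "relative fraction %.4g of species %s reaches phi_m = %.4g: effective viscosity is singular",
      max(rel), names(rel)[which.max(rel)], phi_m), call. = FALSE)
  }
  eta0 * prod((1 - rel / phi_m)^(-2))
}

#' Effective viscosity of a multi-species suspension (cyclic mixture rule)
#'
#' Weighted average of the component viscosities of the suspension: the pure
#' solvent (`eta0`) and, for each solute `j`, the viscosity `eta_j` of that
#' solute suspended in the medium formed by the solvent and all other
#' solutes. Each `eta_j` is a nested Quemada cascade over the cyclic chain
#' described in [relative_solute_fractions()]; the cyclic permutations keep
#' the construction even-handed across species, and swapping the labels of
#' two species leaves the result unchanged. The averaging weights follow the
#' composition's normalization mode (see [mixture_composition()]).
#'
#' @param composition A [mixture_composition()].
#' @param eta0 Solvent viscosity (Pa s).
#' @param phi_m Maximum packing fraction (default 0.6).
#' @return Effective viscosity `eta_e` (Pa s). Always `>= eta0`, with
#'   equality exactly when all solute fractions vanish; errors if any
#'   relative fraction reaches `phi_m`.
#' @examples
#' comp <- mixture_composition(0.0192)
#' mixture_effective_viscosity(comp, eta0 = 0.89e-3)  # ~8.91e-4 Pa s
#' @export
mixture_effective_viscosity <- function(composition, eta0 = 0.89e-3,
                                        phi_m = 0.6) {
  stopifnot(inherits(composition, "mixture_composition"))
  .check_positive(eta0 = eta0, phi_m = phi_m)
  phi <- composition$phi
  n <- length(phi)
  if (n == 0L || sum(phi) == 0) return(eta0)
  eta_j <- vapply(seq_len(n), function(j) {
    .component_viscosity(composition, j, eta0, phi_m)
  }, numeric(1))
  if (composition$normalization == "solute_normalized") {
    psi <- phi / sum(phi)
    sum(psi * eta_j)
  } else {
    composition$phi0 * eta0 + sum(phi * eta_j)
  }
}

#' Effective viscosity of a bidisperse sphere-rod suspension
#'
#' Empirical model for a suspension of small spheres and much longer rods
#' (`(L/2)/a_s > 20`): the spheres are so much smaller that the rods sense
#' the sphere suspension as a homogeneous Newtonian background. The
#' viscosity composes multiplicatively,
#' \deqn{\eta = \eta_{rel,r}(\phi_r)\; \eta_{rel,s}(\hat\phi_s)\; \eta_0,}
#' with `phi_hat_s = phi_s / (phi0 + phi_s)` the sphere fraction relative to
#' the rod-free suspension. The sphere factor uses the Thomas hard-sphere
#' correlation, offset-corrected so that zero loading gives exactly the
#' background viscosity: `1 + 2.5 x + 10.05 x^2 + 0.00273 (exp(16.6 x) - 1)`. The rod factor
#' has two concentration regimes split at `phi_r = 0.125` (the dilute branch
#' applies at the boundary): a dilute linear law `1 + [eta] phi_r` with
#' slender-rod intrinsic viscosity `[eta] = 2.5 + (4/15) r^2 / log(r)`
#' (`r = L/d`), continued for `phi_r > 0.125` by a crowding factor
#' `((1 - 0.125/phi_m) / (1 - phi_r/phi_m))^2` that keeps the model
#' continuous and diverges at `phi_m`.
#'
#' @param phi_r Rod volume fraction (>= 0).
#' @param phi_s Sphere volume fraction (>= 0).
#' @param rod A [rod_shape()].
#' @param sphere A [sphere_shape()].
#' @param eta0 Solvent viscosity (Pa s).
#' @param phi_m Packing fraction for the crowded-rod branch (default 0.6).
#' @return Effective viscosity (Pa s) with attribute `branch` in
#'   `"dilute"`/`"semidilute"` recording the rod regime used.
#' @export
sphere_rod_effective_viscosity <- function(phi_r, phi_s, rod, sphere,
                                           eta0 = 0.89e-3, phi_m = 0.6) {
  stopifnot(inherits(rod, "rod_shape"), inherits(sphere, "sphere_shape"))
  .check_positive(eta0 = eta0, phi_m = phi_m)
  if (phi_r < 0 || phi_s < 0) {
    stop("volume fractions must be nonnegative", call. = FALSE)
  }
  if (phi_r + phi_s >= 1) {
    stop("solute volume fractions must sum to less than 1", call. = FALSE)
  }
  a_r <- rod$L / 2
  if (a_r / sphere$a <= 20) {
    stop("sphere-rod model requires rod semi-length / sphere radius > 20",
         call. = FALSE)
  }
  phi0 <- 1 - phi_r - phi_s
  phi_hat_s <- if (phi_s > 0) phi_s / (phi0 + phi_s) else 0
  eta_rel_s <- 1 + 2.5 * phi_hat_s + 10.05 * phi_hat_s^2 +
    0.00273 * (exp(16.6 * phi_hat_s) - 1)
  r <- rod$L / rod$d
  intrinsic <- 2.5 + (4 / 15) * r^2 / log(r)
  if (phi_r <= 0.125) {
    eta_rel_r <- 1 + intrinsic * phi_r
    branch <- "dilute"
  } else {
    if (phi_r >= phi_m) {
      stop(sprintf("rod fraction %.4g reaches phi_m = %.4g: viscosity is singular",
                   phi_r, phi_m), call. = FALSE)
    }
    eta_rel_r <- (1 + intrinsic * 0.125) *
      ((1 - 0.125 / phi_m) / (1 - phi_r / phi_m))^2
    branch <- "semidilute"
  }
  structure(eta_rel_r * eta_rel_s * eta0, branch = branch)
}
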