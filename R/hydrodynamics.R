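#' Stokes drag coefficients for spheres, prolate spheroids, and rods
#'
#' Translational drag coefficients `f` (N s/m) at low Reynolds number, such
#' that the Stokes-Einstein diffusion coefficient is `k_B T / f`. Spheres
#' have the isotropic `f = 6 pi eta a`. Prolate spheroids are
#' orientation-resolved using the Chwang-Wu closed forms, with
#' `e = sqrt(1 - b^2/c^2)` and `Lg = log((1 + e)/(1 - e))`:
#' \deqn{f_\parallel = \frac{16\pi\eta c e^3}{(1+e^2)\,Lg - 2e}, \qquad
#'       f_\perp    = \frac{32\pi\eta c e^3}{2e + (3e^2-1)\,Lg}.}
#' Both reduce to `6 pi eta c` as `e -> 0`, and `f_perp > f_par` for any
#' `e > 0`, which is what turns one spheroid geometry into a pair of
#' diffusion bounds.
#'
#' @param a Sphere radius (m).
#' @param shape A [spheroid_shape()] (`spheroid_drag_*`) or [rod_shape()]
#'   (`rod_shape_factor`).
#' @param eta Dynamic viscosity of the surrounding medium (Pa s).
#' @return A `drag_coefficient` object: list with `value` (N s/m) and
#'   `orientation` in `"isotropic"`, `"parallel"`, `"perpendicular"`.
#' @examples
#' pf <- spheroid_shape(300e-9, 2.25e-9)
#' equivalent_radius(spheroid_drag_parallel(pf, 0.89e-3), 0.89e-3)  # ~39.3 nm
#' @export
sphere_drag <- function(a, eta) {
  .check_positive(a = a, eta = eta)
  drag_coefficient(6 * pi * eta * a, "isotropic")
}

drag_coefficient <- function(value, orientation) {
  structure(list(value = value, orientation = orientation),
            class = "drag_coefficient")
}

#' @export
print.drag_coefficient <- function(x, ...) {
  cat(sprintf("<drag_coefficient> %.6g N s/m (%s)\n", x$value, x$orientation))
  invisible(x)
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a positive finite number", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Shared Chwang-Wu evaluation. The closed forms are 0/0 as e -> 0 and their
# denominators lose ~e^-2 digits to cancellation, so below e = 1e-3 the
# second-order sphere-limit series (relative error < e^4) is used instead;
# Lg is evaluated as 2*atanh(e) to keep its absolute rounding O(e * eps).
.chwang_wu <- function(shape, eta, orientation) {
  stopifnot(inherits(shape, "spheroid_shape"))
  .check_positive(eta = eta)
  e <- eccentricity(shape)
  f0 <- 6 * pi * eta * shape$c
  if (e < 1e-3) {
    coef <- if (orientation == "parallel") 2 / 5 else 3 / 10
    return(drag_coefficient(f0 * (1 - coef * e^2), orientation))
  }
  Lg <- 2 * atanh(e)
  f <- if (orientation == "parallel") {
    16 * pi * eta * shape$c * e^3 / ((1 + e^2) * Lg - 2 * e)
  } else {
    32 * pi * eta * shape$c * e^3 / (2 * e + (3 * e^2 - 1) * Lg)
  }
  drag_coefficient(f, orientation)
}

#' @rdname sphere_drag
#' @export
spheroid_drag_parallel <- function(shape, eta) {
  .chwang_wu(shape, eta, "parallel")
}

#' @rdname sphere_drag
#' @export
spheroid_drag_perpendicular <- function(shape, eta) {
  .chwang_wu(shape, eta, "perpendicular")
}

#' @rdname sphere_drag
#' @param orientation `"parallel"` (translation along the rod axis) or
#'   `"perpendicular"`.
#' @details `rod_shape_factor` returns the dimensionless slender-body factor
#'   `S` such that the rod drag is `f = S * eta * L`: leading order
#'   `S_par = 2 pi / log(L/d)` and `S_perp = 4 pi / log(L/d)`, so the
#'   perpendicular/parallel ratio tends to 2 for long rods. Requires
#'   `L/d > 1`.
#' @export
rod_shape_factor <- function(shape, orientation = c("parallel",
                                                    "perpendicular")) {
  stopifnot(inherits(shape, "rod_shape"))
  orientation <- match.arg(orientation)
  ratio <- shape$L / shape$d
  if (ratio <= 1) stop("rod aspect ratio L/d must exceed 1", call. = FALSE)
  base <- 2 * pi / log(ratio)
  if (orientation == "perpendicular") 2 * base else base
}

#' Equivalent Stokes radius of a drag coefficient
#'
#' Radius of the sphere with the same drag: `a_eq = f / (6 pi eta)`. This is
#' the hydrodynamic radius a Stokes-Einstein inversion of a measured
#' diffusion coefficient would report.
#'
#' @param f A `drag_coefficient` or a bare numeric drag (N s/m).
#' @param eta Viscosity used in the inversion (Pa s).
#' @return Equivalent radius (m).
#' @export
equivalent_radius <- function(f, eta) {
  if (inherits(f, "drag_coefficient")) f <- f$value
  .check_positive(f = f, eta = eta)
  f / (6 * pi * eta)
}
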