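#' Particle shape constructors
#'
#' Aggregating amyloid-beta species are represented by simple convex
#' envelopes: spheres (radius `a`), prolate spheroids (semi-major axis `c`
#' along the fibril axis, semi-minor axis `b`), and rigid rods (length `L`,
#' diameter `d`). All lengths are in metres.
#'
#' @param a Sphere radius (m), `a > 0`.
#' @param c Spheroid semi-major axis (m), `c >= b`.
#' @param b Spheroid semi-minor axis (m), `b > 0`.
#' @param L Rod length (m), `L > d`.
#' @param d Rod diameter (m), `d > 0`.
#'
#' @return An object of class `sphere_shape`, `spheroid_shape`, or
#'   `rod_shape`; a list carrying the validated dimensions.
#' @examples
#' spheroid_shape(c = 300e-9, b = 2.25e-9)  # a 1600-mer protofibril envelope
#' @export
sphere_shape <- function(a) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  if (a <= 0) stop("sphere radius 'a' must be positive", call. = FALSE)
  structure(list(a = a), class = c("sphere_shape", "particle_shape"))
}

#' @rdname sphere_shape
#' @export
spheroid_shape <- function(c, b) {
  stopifnot(is.numeric(c), is.numeric(b), length(c) == 1L, length(b) == 1L,
            is.finite(c), is.finite(b))
  if (b <= 0) stop("semi-minor axis 'b' must be positive", call. = FALSE)
  if (c < b) stop("semi-major axis 'c' must satisfy c >= b", call. = FALSE)
  structure(list(c = c, b = b), class = c("spheroid_shape", "particle_shape"))
}

#' @rdname sphere_shape
#' @export
rod_shape <- function(L, d) {
  stopifnot(is.numeric(L), is.numeric(d), length(L) == 1L, length(d) == 1L,
            is.finite(L), is.finite(d))
  if (d <= 0) stop("rod diameter 'd' must be positive", call. = FALSE)
  if (L <= d) stop("rod length 'L' must exceed its diameter 'd'",
                   call. = FALSE)
  structure(list(L = L, d = d), class = c("rod_shape", "particle_shape"))
}

#' @export
print.particle_shape <- function(x, ...) {
  dims <- vapply(x, function(v) format(v, digits = 4), character(1))
  cat(sprintf("<%s> %s\n", class(x)[1L],
              paste(names(dims), dims, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Volume of a particle envelope
#'
#' Prolate spheroid volume `(4/3) pi c b^2`; sphere volume `(4/3) pi a^3`.
#'
#' @param shape A `spheroid_shape` or `sphere_shape`.
#' @return Volume in m^3.
#' @examples
#' spheroid_volume(spheroid_shape(300e-9, 2.25e-9))  # ~6.36e-24 m^3
#' @export
spheroid_volume <- function(shape) {
  if (inherits(shape, "sphere_shape")) return(4 / 3 * pi * shape$a^3)
  stopifnot(inherits(shape, "spheroid_shape"))
  4 / 3 * pi * shape$c * shape$b^2
}

#' Eccentricity of a prolate spheroid
#'
#' `e = sqrt(1 - b^2/c^2)`, in `[0, 1)`; 0 for a sphere (`b = c`), tending
#' to 1 for a slender filament.
#'
#' @param shape A `spheroid_shape`.
#' @return Dimensionless eccentricity.
#' @export
eccentricity <- function(shape) {
  stopifnot(inherits(shape, "spheroid_shape"))
  sqrt(1 - (shape$b / shape$c)^2)
}

#' Lateral association of spheroidal protofibrils
#'
#' Side-by-side association of n copies of a protofibril envelope leaves the
#' major axis unchanged and multiplies the minor axis by n: the n-fold
#' associated species is enveloped by a spheroid with semi-axes `(c, n*b)`.
#' This is the geometric composition rule for the lateral-association
#' pathway; because `c/b` is large the enveloping spheroid remains prolate
#' for all multiplicities of interest.
#'
#' @param base A `spheroid_shape`, the single-protofibril envelope.
#' @param n Integer multiplicity, `n >= 1`.
#' @return A `spheroid_shape` with semi-axes `(c, n*b)`.
#' @examples
#' laterally_associate(spheroid_shape(300e-9, 2.25e-9), 2)  # b -> 4.5 nm
#' @export
laterally_associate <- function(base, n) {
  stopifnot(inherits(base, "spheroid_shape"), is.numeric(n), length(n) == 1L)
  if (n < 1 || n != round(n)) {
    stop("multiplicity 'n' must be an integer >= 1", call. = FALSE)
  }
  spheroid_shape(c = base$c, b = n * base$b)
}

#' Geometry of the laterally associated species ladder
#'
#' Builds the per-species geometry for species `n = 1, ..., n_max`, where
#' species n is an (n x 1600)-mer whose envelope is
#' `laterally_associate(base, n)`. The per-particle volume is, by default,
#' the volume of the enveloping spheroid ("envelope" mode; note this grows
#' as n^2 while monomer mass grows as n, since side-by-side spheroids do not
#' fill their envelope). The alternative "mass" mode assigns n times the
#' base envelope volume, for sensitivity analysis of the volume-fraction
#' bookkeeping.
#'
#' @param n_max Number of species, `n_max >= 1`.
#' @param base A `spheroid_shape` for the 1600-mer protofibril.
#' @param volume_mode `"envelope"` (default) or `"mass"`.
#' @param monomers_per_base Monomer count of the base species (default 1600).
#' @return A list of `species_geometry` objects with fields `n`, `shape`,
#'   `particle_volume` (m^3), and `monomer_count`.
#' @examples
#' geoms <- build_species_geometries(5, spheroid_shape(300e-9, 2.25e-9))
#' sapply(geoms, function(g) g$shape$b)  # 2.25, 4.5, ..., 11.25 nm
#' @export
build_species_geometries <- function(n_max, base,
                                     volume_mode = c("envelope", "mass"),
                                     monomers_per_base = 1600L) {
  stopifnot(is.numeric(n_max), length(n_max) == 1L, n_max >= 1,
            n_max == round(n_max), inherits(base, "spheroid_shape"))
  volume_mode <- match.arg(volume_mode)
  base_volume <- spheroid_volume(base)
  lapply(seq_len(n_max), function(n) {
    shp <- laterally_associate(base, n)
    vol <- switch(volume_mode,
                  envelope = spheroid_volume(shp),
                  mass = n * base_volume)
    structure(list(n = n, shape = shp, particle_volume = vol,
                   monomer_count = as.integer(monomers_per_base) * n),
              class = "species_geometry")
  })
}

#' @export
print.species_geometry <- function(x, ...) {
  cat(sprintf("<species_geometry> %d-mer of base units (n = %d), volume %.4g m^3\n",
              x$monomer_count, x$n, x$particle_volume))
  invisible(x)
}
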