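#' Configuration for a lateral-association case study
#'
#' Bundles every knob of the end-to-end computation: the reaction network
#' size, initial protofibril concentration, rate constants, the base
#' protofibril envelope, solvent/thermo parameters, the viscosity
#' conventions, and the output time grid. Defaults reproduce the 5-species
#' case study: 5 uM of 1600-mers, `k_plus = 0.9 h^-1 mM^-1`,
#' `k_minus = 6e-3 h^-1`, spheroid semi-axes 300 nm x 2.25 nm, water at
#' room temperature, `phi_m = 0.6`, 91 time points over 0-90 min.
#'
#' @param n_species Number of species (>= 2).
#' @param init_conc_uM Initial 1600-mer concentration (uM); all larger
#'   species start at zero.
#' @param k_plus,k_minus Rate constants (h^-1 mM^-1, h^-1).
#' @param semi_major_nm,semi_minor_nm Base protofibril spheroid semi-axes
#'   (nm).
#' @param eta0 Solvent viscosity (Pa s).
#' @param phi_m Maximum packing fraction.
#' @param temperature Absolute temperature (K).
#' @param t_end_min End of the time grid (minutes).
#' @param n_timepoints Number of output times (inclusive of 0 and
#'   `t_end_min`).
#' @param volume_mode `"mass"` (default) or `"envelope"`; see
#'   [build_species_geometries()]. The case studies book-keep suspension
#'   volume with the occupied (mass-proportional) volume, `n` times the
#'   protofibril volume: the enveloping spheroid is a hydrodynamic shape,
#'   not a volume measure, and its n^2 growth would make the total solute
#'   fraction rise during association, reversing the viscosity trend.
#' @param fraction_mode `"solute_normalized"` (case-study default) or
#'   `"absolute"`; see [mixture_composition()].
#' @param rtol,atol Kinetics solver tolerances.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_species = 5, init_conc_uM = 5,
                              k_plus = 0.9, k_minus = 6e-3,
                              semi_major_nm = 300, semi_minor_nm = 2.25,
                              eta0 = 0.89e-3, phi_m = 0.6,
                              temperature = 298.15,
                              t_end_min = 90, n_timepoints = 91,
                              volume_mode = c("mass", "envelope"),
                              fraction_mode = c("solute_normalized",
                                                "absolute"),
                              rtol = 1e-8, atol = 1e-12) {
  volume_mode <- match.arg(volume_mode)
  fraction_mode <- match.arg(fraction_mode)
  if (n_species < 2 || n_species != round(n_species)) {
    stop("'n_species' must be an integer >= 2", call. = FALSE)
  }
  .check_positive(init_conc_uM = init_conc_uM,
                  semi_major_nm = semi_major_nm,
                  semi_minor_nm = semi_minor_nm, eta0 = eta0,
                  phi_m = phi_m, temperature = temperature,
                  t_end_min = t_end_min)
  if (n_timepoints < 2) stop("'n_timepoints' must be >= 2", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 init_conc_uM = init_conc_uM,
                 k_plus = k_plus, k_minus = k_minus,
                 semi_major_nm = semi_major_nm,
                 semi_minor_nm = semi_minor_nm,
                 eta0 = eta0, phi_m = phi_m, temperature = temperature,
                 t_end_min = t_end_min,
                 n_timepoints = as.integer(n_timepoints),
                 volume_mode = volume_mode, fraction_mode = fraction_mode,
                 rtol = rtol, atol = atol),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d species, %g uM over 0-%g min (%d points)\n",
    x$n_species, x$init_conc_uM, x$t_end_min, x$n_timepoints))
  cat(sprintf("  k+ = %g /h/mM, k- = %g /h; spheroid %g x %g nm (%s volumes)\n",
              x$k_plus, x$k_minus, x$semi_major_nm, x$semi_minor_nm,
              x$volume_mode))
  cat(sprintf("  eta0 = %g Pa s, phi_m = %g, T = %g K, %s fractions\n",
              x$eta0, x$phi_m, x$temperature, x$fraction_mode))
  invisible(x)
}

.config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Run a lateral-association case study end to end
#'
#' Integrates the association kinetics, converts each state to volume
#' fractions, evaluates the cyclic-mixture effective viscosity and the
#' per-species upper/lower effective diffusion coefficients at every time
#' point. Deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @param verbose If `TRUE`, log the configuration hash, solver diagnostics
#'   and the range of every output column.
#' @return A `lateral_assoc_sim` object; its `results` element is a
#'   data.frame with one row per time point: `time_min`, per-species
#'   concentrations `F*_uM`, `eta_e_pa_s`, and per-species `k_lower_*`,
#'   `k_upper_*` (m^2/s).
#' @examples
#' \donttest{
#' sim <- run_case(simulation_config(n_species = 2, n_timepoints = 10))
#' summary(sim)
#' }
#' @export
run_case <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  base <- spheroid_shape(config$semi_major_nm * 1e-9,
                         config$semi_minor_nm * 1e-9)
  geoms <- build_species_geometries(config$n_species, base,
                                    volume_mode = config$volume_mode)
  network <- build_reaction_network(config$n_species)
  rates <- rate_constants(config$k_plus, config$k_minus)
  times_min <- seq(0, config$t_end_min, length.out = config$n_timepoints)
  init <- c(config$init_conc_uM, numeric(config$n_species - 1L))
  traj <- simulate_kinetics(network, rates, init = init,
                            times = times_min / 60, unit = "uM",
                            rtol = config$rtol, atol = config$atol)
  species_lab <- colnames(traj$conc)
  rows <- lapply(seq_along(times_min), function(k) {
    state <- traj$conc[k, ]
    comp <- concentrations_to_volume_fractions(
      state, geoms, normalization = config$fraction_mode)
    bounds <- effective_diffusion_bounds(comp, geoms, eta0 = config$eta0,
                                         phi_m = config$phi_m,
                                         temperature = config$temperature)
    c(time_min = times_min[k],
      stats::setNames(1000 * state, paste0(species_lab, "_uM")),
      eta_e_pa_s = bounds$eta_e[1L],
      stats::setNames(bounds$k_lower, paste0("k_lower_", species_lab)),
      stats::setNames(bounds$k_upper, paste0("k_upper_", species_lab)))
  })
  results <- as.data.frame(do.call(rbind, rows))
  sim <- structure(list(results = results, config = config,
                        trajectory = traj, geometries = geoms),
                   class = "lateral_assoc_sim")
  if (verbose) {
    message(sprintf("run_case: config %s; solver istate %d",
                    .config_hash(config), traj$diagnostics$istate))
    for (nm in names(results)) {
      message(sprintf("  %-18s min %.6g  max %.6g", nm,
                      min(results[[nm]]), max(results[[nm]])))
    }
  }
  sim
}

#' @export
print.lateral_assoc_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lateral_assoc_sim> %d-species case, %g uM, 0-%g min (%d rows)\n",
    cfg$n_species, cfg$init_conc_uM, cfg$t_end_min, nrow(x$results)))
  kl <- grep("^k_lower_", names(x$results), value = TRUE)
  ku <- grep("^k_upper_", names(x$results), value = TRUE)
  cat(sprintf("  eta_e: %.4g-%.4g Pa s; k_e bounds: %.4g-%.4g m^2/s\n",
              min(x$results$eta_e_pa_s), max(x$results$eta_e_pa_s),
              min(as.matrix(x$results[kl])), max(as.matrix(x$results[ku]))))
  invisible(x)
}

#' @export
summary.lateral_assoc_sim <- function(object, ...) {
  res <- object$results
  conc_cols <- grep("_uM$", names(res), value = TRUE)
  last <- nrow(res)
  cat(sprintf("Lateral association, %d species at %g uM (0-%g min)\n",
              object$config$n_species, object$config$init_conc_uM,
              object$config$t_end_min))
  cat("Concentrations (uM), first -> last time point:\n")
  for (nm in conc_cols) {
    cat(sprintf("  %-10s %.6g -> %.6g\n", sub("_uM$", "", nm),
                res[[nm]][1L], res[[nm]][last]))
  }
  cat(sprintf("Effective viscosity: %.6g -> %.6g Pa s\n",
              res$eta_e_pa_s[1L], res$eta_e_pa_s[last]))
  kl <- grep("^k_lower_", names(res), value = TRUE)
  ku <- grep("^k_upper_", names(res), value = TRUE)
  cat(sprintf("Diffusion bounds over the run: [%.6g, %.6g] m^2/s\n",
              min(as.matrix(res[kl])), max(as.matrix(res[ku]))))
  invisible(object)
}

#' @export
as.data.frame.lateral_assoc_sim <- function(x, ...) x$results

#' @export
plot.lateral_assoc_sim <- function(x, ...) {
  res <- x$results
  conc_cols <- grep("_uM$", names(res), value = TRUE)
  kl <- grep("^k_lower_", names(res), value = TRUE)
  ku <- grep("^k_upper_", names(res), value = TRUE)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(res$time_min, as.matrix(res[conc_cols]), type = "l",
                    lty = 1, xlab = "time (min)",
                    ylab = "concentration (uM)",
                    main = "species concentrations", ...)
  graphics::legend("right", legend = sub("_uM$", "", conc_cols),
                   col = seq_along(conc_cols), lty = 1, bty = "n",
                   cex = 0.8)
  first <- c(kl[1L], ku[1L])
  lastb <- c(kl[length(kl)], ku[length(ku)])
  graphics::matplot(res$time_min, as.matrix(res[c(first, lastb)]),
                    type = "l", lty = c(1, 2, 1, 2),
                    col = c(1, 1, 2, 2), xlab = "time (min)",
                    ylab = "k_e (m^2/s)",
                    main = "diffusion bounds (smallest/largest)", ...)
  invisible(x)
}

#' Write and read case-study results tables
#'
#' `write_results` stores the results of [run_case()] (or any data.frame)
#' as plain CSV with 12 significant digits, enough for a lossless round
#' trip at that precision; `read_results` reads it back.
#'
#' @param table A `lateral_assoc_sim` or data.frame.
#' @param path File path.
#' @return `write_results`: the path, invisibly. `read_results`: a
#'   data.frame.
#' @export
write_results <- function(table, path) {
  if (inherits(table, "lateral_assoc_sim")) table <- table$results
  stopifnot(is.data.frame(table))
  formatted <- as.data.frame(lapply(table, function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else col
  }), check.names = FALSE)
  utils::write.csv(formatted, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read a DLS-style diffusion trace
#'
#' Reads a two-column CSV (header expected) of time versus diffusion
#' coefficient, the format DLS instrument software exports. Non-monotone
#' time stamps are sorted with a warning; an empty file or a file whose
#' rows are not two numeric fields is an error naming the offending line.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `time` and `D`.
#' @export
read_dls_trace <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    stop(sprintf("'%s' contains no data rows", path), call. = FALSE)
  }
  body <- lines[-1L]
  parsed <- lapply(seq_along(body), function(k) {
    fields <- strsplit(body[k], ",", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("cannot parse line %d of '%s': \"%s\"",
                   k + 1L, path, body[k]), call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, parsed)
  out <- data.frame(time = m[, 1L], D = m[, 2L])
  if (is.unsorted(out$time, strictly = FALSE)) {
    warning("DLS trace times are not monotone; sorting by time",
            call. = FALSE)
    out <- out[order(out$time), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Synthesize a noisy DLS-like trace from model output
#'
#' Takes a model diffusion series (by default the lower-limit coefficient
#' of the smallest species, the quantity closest to what DLS reports for an
#' associating suspension) and perturbs it with multiplicative lognormal
#' noise of coefficient of variation `noise_cv` (mean 1), emulating
#' instrument scatter. Reproducible for a fixed `seed`.
#'
#' @param table A `lateral_assoc_sim` or its results data.frame.
#' @param noise_cv Coefficient of variation of the noise, `>= 0`.
#' @param seed Integer seed for the noise draw.
#' @param column Name of the series to perturb; default the first
#'   `k_lower_*` column.
#' @return A data.frame with columns `time` and `D`.
#' @export
generate_synthetic_dls <- function(table, noise_cv = 0.1, seed = 1L,
                                   column = NULL) {
  if (inherits(table, "lateral_assoc_sim")) table <- table$results
  stopifnot(is.data.frame(table))
  if (noise_cv < 0) stop("'noise_cv' must be nonnegative", call. = FALSE)
  if (is.null(column)) {
    column <- grep("^k_lower_", names(table), value = TRUE)[1L]
  }
  if (is.na(column) || !column %in% names(table)) {
    stop("no diffusion series column found in 'table'", call. = FALSE)
  }
  series <- table[[column]]
  if (noise_cv == 0) {
    noise <- rep(1, length(series))
  } else {
    set.seed(seed)
    sdlog <- sqrt(log1p(noise_cv^2))
    noise <- stats::rlnorm(length(series), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  }
  data.frame(time = table$time_min, D = series * noise)
}
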