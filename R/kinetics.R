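#' Rate constants for reversible lateral association
#'
#' Forward (`k_plus`, h^-1 mM^-1) and backward (`k_minus`, h^-1) rate
#' constants shared by every association reaction
#' `F_{i*1600} + F_{j*1600} <-> F_{(i+j)*1600}`. Defaults are the validated
#' lateral-association values `k_plus = 0.9 h^-1 mM^-1` and
#' `k_minus = 6e-3 h^-1`.
#'
#' @param k_plus Forward rate constant (h^-1 mM^-1), `>= 0`.
#' @param k_minus Backward rate constant (h^-1), `>= 0`.
#' @return A `rate_constants` object.
#' @export
rate_constants <- function(k_plus = 0.9, k_minus = 6e-3) {
  stopifnot(is.numeric(k_plus), is.numeric(k_minus),
            length(k_plus) == 1L, length(k_minus) == 1L)
  if (k_plus < 0 || k_minus < 0) {
    stop("rate constants must be nonnegative", call. = FALSE)
  }
  structure(list(k_plus = k_plus, k_minus = k_minus),
            class = "rate_constants")
}

#' Lateral-association reaction network
#'
#' Enumerates the reversible reactions
#' `F_{i*1600} + F_{j*1600} <-> F_{(i+j)*1600}` among species `1..n_max`
#' (species n being the (n x 1600)-mer): all ordered pairs `(i, j)` with
#' `i <= j` and `i + j <= n_max`. The cap enforces the closure assumption
#' that no species beyond `F_{n_max*1600}` forms on the observed timescale.
#'
#' @param n_max Number of species, `>= 2`.
#' @return A `reaction_network`: list with `n_max` and `reactions`, a
#'   two-column integer matrix of `(i, j)` pairs.
#' @examples
#' build_reaction_network(5)$reactions  # (1,1) (1,2) (1,3) (1,4) (2,2) (2,3)
#' @export
build_reaction_network <- function(n_max) {
  stopifnot(is.numeric(n_max), length(n_max) == 1L)
  if (n_max < 2 || n_max != round(n_max)) {
    stop("'n_max' must be an integer >= 2", call. = FALSE)
  }
  n_max <- as.integer(n_max)
  pairs <- list()
  for (i in seq_len(n_max)) {
    for (j in i:n_max) {
      if (i + j <= n_max) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  reactions <- do.call(rbind, pairs)
  colnames(reactions) <- c("i", "j")
  structure(list(n_max = n_max, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  rx <- apply(x$reactions, 1L, function(p) {
    sprintf("F%d + F%d <-> F%d", 1600 * p[1], 1600 * p[2],
            1600 * (p[1] + p[2]))
  })
  cat(sprintf("<reaction_network> %d species, %d reversible reactions:\n  %s\n",
              x$n_max, nrow(x$reactions), paste(rx, collapse = "\n  ")))
  invisible(x)
}

.check_state <- function(state, n_max) {
  stopifnot(is.numeric(state))
  if (length(state) != n_max) {
    stop(sprintf("state must have %d concentrations (got %d)",
                 n_max, length(state)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Net flux of one association reaction
#'
#' Mass-action net flux of `F_i + F_j <-> F_{i+j}` (species indexed by
#' multiplicity): `R(i, j) = k_plus [F_i][F_j] - k_minus [F_{i+j}]`, in
#' mM/h with concentrations in mM.
#'
#' @param state Numeric vector of species concentrations (mM), species
#'   `1..n_max`.
#' @param rates A [rate_constants()].
#' @param i,j Reactant multiplicities; `(i, j)` must be a reaction of
#'   `network`.
#' @param network The [build_reaction_network()] the reaction belongs to.
#' @return Net flux (mM/h); positive when association dominates.
#' @export
reaction_flux <- function(state, rates, i, j, network) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(network, "reaction_network"))
  .check_state(state, network$n_max)
  ok <- any(network$reactions[, "i"] == i & network$reactions[, "j"] == j)
  if (!ok) {
    stop(sprintf("(%s, %s) is not a reaction of this network", i, j),
         call. = FALSE)
  }
  rates$k_plus * state[i] * state[j] - rates$k_minus * state[i + j]
}

#' Right-hand side of the lateral-association ODE system
#'
#' Material balance over all reactions: each reaction `(i, j)` with net flux
#' `R` consumes species `i` and `j` at rate `R` each (so homodimerization
#' `2 F_i -> F_2i` consumes species `i` at `2R` - the unique stoichiometry
#' that conserves monomer mass) and produces species `i + j` at rate `R`.
#'
#' @inheritParams reaction_flux
#' @return Numeric vector `d[state]/dt` (mM/h).
#' @export
kinetics_rhs <- function(state, network, rates) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(rates, "rate_constants"))
  .check_state(state, network$n_max)
  dC <- numeric(network$n_max)
  for (r in seq_len(nrow(network$reactions))) {
    i <- network$reactions[r, "i"]
    j <- network$reactions[r, "j"]
    R <- rates$k_plus * state[i] * state[j] - rates$k_minus * state[i + j]
    dC[i] <- dC[i] - R
    dC[j] <- dC[j] - R
    dC[i + j] <- dC[i + j] + R
  }
  dC
}

#' Total monomer mass of a kinetic state
#'
#' Conserved quantity of the association network, in 1600-mer equivalents:
#' `sum_i i * [F_{i*1600}]` (mM). Constant along any trajectory.
#'
#' @param state Numeric vector of concentrations (mM), or a
#'   `kinetics_trajectory` (in which case one value per time point is
#'   returned).
#' @return Total monomer mass (mM of 1600-mer equivalents).
#' @export
total_monomer_mass <- function(state) {
  if (inherits(state, "kinetics_trajectory")) {
    return(as.numeric(state$conc %*% seq_len(ncol(state$conc))))
  }
  stopifnot(is.numeric(state))
  sum(seq_along(state) * state)
}

#' Integrate the lateral-association kinetics
#'
#' Stiff-capable initial-value integration of the mass-action system
#' defined by [kinetics_rhs()], via `deSolve::ode` (lsoda, which switches
#' to a backward-differentiation method when the problem is stiff). Tight
#' default tolerances (`rtol = 1e-8`, `atol = 1e-12` mM) keep the
#' monomer-mass conservation check meaningful.
#'
#' @param network A [build_reaction_network()].
#' @param rates A [rate_constants()].
#' @param init Initial concentrations (species `1..n_max`). In mM unless
#'   `unit = "uM"`.
#' @param times Strictly increasing output times (hours).
#' @param rtol,atol Solver tolerances (atol in mM).
#' @param unit Unit of `init`: `"mM"` (default) or `"uM"`.
#' @return A `kinetics_trajectory`: list with `times` (h), `conc` (time x
#'   species matrix, mM; columns `F1600`, `F3200`, ...), `network`, `rates`,
#'   and `diagnostics` from the solver.
#' @examples
#' net <- build_reaction_network(2)
#' tr <- simulate_kinetics(net, rate_constants(), init = c(5, 0),
#'                         times = seq(0, 1.5, by = 0.25), unit = "uM")
#' tr$conc[, "F1600"]  # slowly decaying, mM
#' @export
simulate_kinetics <- function(network, rates, init, times,
                              rtol = 1e-8, atol = 1e-12,
                              unit = c("mM", "uM")) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(rates, "rate_constants"))
  unit <- match.arg(unit)
  .check_state(init, network$n_max)
  if (any(init < 0)) stop("initial concentrations must be nonnegative",
                          call. = FALSE)
  if (unit == "uM") init <- init / 1000
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  rhs <- function(t, y, parms) list(kinetics_rhs(y, network, rates))
  out <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  if (istate < 0 || nrow(out) < length(times) || anyNA(out)) {
    detail <- paste(utils::capture.output(deSolve::diagnostics(out)),
                    collapse = " ")
    stop(sprintf("kinetics integration failed (istate = %d); %s",
                 istate, detail), call. = FALSE)
  }
  conc <- unname(out[, -1L, drop = FALSE])
  colnames(conc) <- paste0("F", 1600L * seq_len(network$n_max))
  structure(list(times = as.numeric(out[, 1L]), conc = conc,
                 network = network, rates = rates,
                 diagnostics = list(istate = istate)),
            class = "kinetics_trajectory")
}

#' @export
print.kinetics_trajectory <- function(x, ...) {
  cat(sprintf(
    "<kinetics_trajectory> %d species, %d time points over %.3g-%.3g h\n",
    ncol(x$conc), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final state (mM): %s\n",
              paste(sprintf("%s = %.4g", colnames(x$conc),
                            x$conc[nrow(x$conc), ]), collapse = ", ")))
  invisible(x)
}
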