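---
title: "A modified Stokes-Einstein model for protofibril lateral association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modified Stokes-Einstein model for protofibril lateral association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyvisc)
```

## The problem

Dynamic light scattering (DLS) and analytical ultracentrifugation report
sizes of aggregating proteins by inverting the classical Stokes-Einstein
relation

$$D = \frac{k_B T}{6 \pi \eta_0 a},$$

which assumes (i) a spherical particle and (ii) a solvent of fixed
viscosity $\eta_0$. Neither assumption holds during the lateral association
of amyloid-beta (A$\beta$42) protofibrils: the species are long, thin
objects, and the suspension around any one particle contains all the other
macromolecules, whose concentrations change as association proceeds.
`amyvisc` implements a model that repairs both assumptions and propagates
reaction kinetics through it, producing time-resolved upper and lower
bounds on each species' effective diffusion coefficient.

The model has four coupled parts, mirroring the package modules:

1. **Geometry.** A protofibril is a 1600-mer modeled as a prolate spheroid
   with semi-axes $c = 300$ nm and $b = 2.25$ nm. Lateral (side-by-side)
   association of $n$ protofibrils is enveloped by a spheroid with the same
   major axis and minor axis $n b$, so species $n$ (an $n \times 1600$-mer)
   has semi-axes $(c, n b)$.
2. **Kinetics.** Species associate reversibly,
   $F_{i \cdot 1600} + F_{j \cdot 1600} \rightleftharpoons
   F_{(i+j)\cdot 1600}$ for all $i \le j$, $i + j \le n_{\max}$, with
   shared mass-action rate constants $k_+ = 0.9\ \mathrm{h^{-1} mM^{-1}}$
   and $k_- = 6 \times 10^{-3}\ \mathrm{h^{-1}}$. The cap $n_{\max}$
   encodes the observation that nothing beyond $F_{8000}$ forms on the
   90-minute timescale.
3. **Viscosity.** The suspension's effective viscosity $\eta_e$ is a
   weighted average of component viscosities built from the Quemada law
   $\eta(\phi) = \eta_0 (1 - \phi/\phi_m)^{-2}$ through a cyclic mixing
   rule (below).
4. **Hydrodynamics.** Each spheroidal species has orientation-resolved
   Stokes drag (Chwang-Wu closed forms), giving
   $k_{upper} = k_B T / f_\parallel(\eta_e)$ and
   $k_{lower} = k_B T / f_\perp(\eta_e)$.

## The cyclic mixture viscosity

For solutes at absolute volume fractions $\phi_1, \dots, \phi_n$ in solvent
fraction $\phi_0 = 1 - \sum_i \phi_i$, the component viscosity $\eta_j$ is
the viscosity of solute $j$ suspended in the medium formed by the solvent
and all the *other* solutes, built recursively: the chain for $j$ is the
cyclic order $j, j+1, \dots, n, 1, \dots, j-1$, and at each layer the
species' fraction is taken relative to the sub-suspension containing it
(the solvent plus that species and everything deeper),

$$\hat\phi_{(p)} = \frac{\phi_{(p)}}{\phi_0 + \sum_{q \ge p} \phi_{(q)}},
\qquad
\eta_j = \eta_0 \prod_p \left(1 - \hat\phi_{(p)}/\phi_m\right)^{-2}.$$

The outermost layer's fraction is the plain absolute fraction (nothing
excluded), and for two species the construction is literally "S1 floating
in a medium of solvent plus S2, which is itself S2 suspended in solvent".
The cyclic permutations keep the recipe even-handed: swapping species
labels leaves $\eta_e$ unchanged, which the test suite checks.

Two averaging conventions are provided:

* **absolute** - $\eta_e = \phi_0 \eta_0 + \sum_j \phi_j \eta_j$, a true
  weighted average over all constituents (weights sum to 1);
* **solute_normalized** (case-study default) - the fluid is discounted and
  the weights are the solute fractions rescaled to sum to one,
  $\eta_e = \sum_j \psi_j \eta_j$ with $\psi_j = \phi_j / \sum_i \phi_i$.
  Only the solutes diffuse, and only their mutual crowding is of interest
  for the effective diffusion coefficient.

With a single solute species the solute-normalized form collapses to
$\eta_e = \eta_0 (1 - \phi/\phi_m)^{-2}$ and the modified diffusion
coefficient to $D = D_{SE} (1 - \phi/\phi_m)^2$, which recovers the
classical relation exactly at $\phi = 0$; its first-order expansion in
$\epsilon = \phi/\phi_0$ is $D \approx D_{SE}(1 - 2\phi/\phi_m)$, accurate
to $O(\epsilon^2)$ (`one_species_limit()`).

The weighted-average form is one of several defensible blends; the package
implements exactly this cyclic recipe and no alternatives.

## Orientation-resolved drag, and a note on prefactors

For a prolate spheroid with eccentricity $e = \sqrt{1 - b^2/c^2}$ and
$L_g = \ln\frac{1+e}{1-e}$, the translational drags are

$$f_\parallel = \frac{16 \pi \eta c e^3}{(1+e^2)L_g - 2e}, \qquad
  f_\perp = \frac{32 \pi \eta c e^3}{2e + (3e^2-1)L_g}.$$

Both reduce to the Stokes sphere drag $6\pi\eta c$ as $e \to 0$, and
$f_\perp > f_\parallel$ for every $e > 0$ - which is exactly why one
geometry yields a diffusion *bracket* rather than a single value. These
prefactors matter: the same expressions circulate with $8\pi$/$16\pi$
numerators, which are low by exactly a factor of two (their $e \to 0$
limit is $3\pi\eta c$, half the Stokes drag). The test suite pins the
implemented forms against an independent Oberbeck elliptic-integral
quadrature oracle and against the sphere limit. No orientational (Perrin)
averaging is performed; the model deliberately reports bounds.

Numerics: the closed forms are $0/0$ as $e \to 0$ and their denominators
lose roughly $e^{-2}$ digits to cancellation, so below $e = 10^{-3}$ the
code switches to the second-order series
$f_\parallel \approx 6\pi\eta c\,(1 - \tfrac{2}{5}e^2)$,
$f_\perp \approx 6\pi\eta c\,(1 - \tfrac{3}{10}e^2)$ (relative error
$< e^4$), and $L_g$ is evaluated as $2\,\mathrm{atanh}(e)$.

## Volume bookkeeping: envelope versus occupied volume

Two side-by-side spheroids do not fill the spheroid that envelopes them:
the envelope volume grows as $n^2$ while the material grows as $n$. The
package therefore distinguishes the *hydrodynamic shape* (always the
envelope spheroid, which is what the drag formulas see) from the *volume
fraction bookkeeping*, with two modes in `build_species_geometries()` and
`simulation_config()`:

* `"mass"` (case-study default): species $n$ occupies $n$ times the
  protofibril volume. Total solute volume is conserved by association, and
  the effective viscosity *declines* as material concentrates into fewer,
  larger particles - larger solutes perturb the flow less than the same
  volume of smaller ones, so $\eta_e$ rises and falls with the 1600-mer
  concentration and moves against the larger species.
* `"envelope"`: species $n$ is assigned its enveloping-spheroid volume
  $n^2 V_1$. Total solute volume then *grows* during association and
  $\eta_e$ rises as the 1600-mers are consumed - the opposite trend. This
  mode is retained for sensitivity analysis of the envelope approximation.

The mass mode is the default because it is the physically consistent
volume measure and the only one whose viscosity-concentration trends match
the behavior of the full model (effective viscosity directly proportional
to the 1600-mer concentration, inversely to the larger species'), which
the acceptance tests assert. At the case-study loading the two modes
differ by less than 0.1% in $\eta_e$ itself.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `semi_major_nm` | 300 | nm | protofibril semi-major axis $c$ |
| `semi_minor_nm` | 2.25 | nm | protofibril semi-minor axis $b$ |
| `k_plus` | 0.9 | h$^{-1}$ mM$^{-1}$ | association rate constant |
| `k_minus` | 6e-3 | h$^{-1}$ | dissociation rate constant |
| `init_conc_uM` | 5 | uM | initial 1600-mer concentration |
| `eta0` | 0.89e-3 | Pa s | solvent (water) viscosity |
| `phi_m` | 0.6 | - | Quemada packing fraction (literature range 0.58-0.69) |
| `temperature` | 298.15 | K | room temperature |
| `t_end_min`, `n_timepoints` | 90, 91 | min | output grid, 1-minute spacing |

The printed axis values are interpreted as the semi-axes that enter the
drag formulas directly; the alternative full-axis reading (150 nm,
1.125 nm) is one configuration change. Reported protofibril contour
lengths vary (values near 64 nm also appear in the literature); 300 nm is
the case-study value and any length is accepted. Physical constants are
CODATA ($k_B = 1.380649\times10^{-23}$ J/K,
$N_A = 6.02214076\times10^{23}$ mol$^{-1}$). Concentrations are held in mM
internally (matching the $k_+$ units; 1 mM = 1 mol/m$^3$ makes the volume
fraction conversion $\phi_i = N_A C_i V_i$ direct), with micromolar
accepted at the interfaces.

Kinetics are integrated with a stiff-capable backward-differentiation
solver (`deSolve`'s lsoda) at `rtol = 1e-8`, `atol = 1e-12` mM - tight
enough that the monomer-mass conservation check ($\sum_i i\,[F_{i\cdot
1600}]$ constant to $10^{-6}$ relative) is meaningful. Degenerate inputs
are rejected rather than repaired: compositions whose relative fractions
reach $\phi_m$ raise a singularity error, spheroids require $c \ge b$, and
the sphere-rod model refuses aspect ratios outside its stated domain.

## The sphere-rod alternative

`sphere_rod_effective_viscosity()` implements the bidisperse empirical
alternative for a suspension of small spheres and long rods (rod
semi-length over sphere radius > 20): the spheres are sensed by the rods
as part of the continuum, so the viscosity composes multiplicatively,
$\eta = \eta_{rel,r}(\phi_r)\,\eta_{rel,s}(\hat\phi_s)\,\eta_0$ with
$\hat\phi_s$ the sphere fraction in the rod-free suspension. The sphere
factor is the Thomas hard-sphere correlation (offset-corrected to equal 1
at zero loading); the rod factor is linear in $\phi_r$ with a slender-rod
intrinsic viscosity in the dilute regime and switches at $\phi_r = 0.125$
(the dilute branch applying at the boundary, for continuity) to a crowding
form that stays continuous and diverges at $\phi_m$. The companion
diffusion relation divides $k_B T$ by the slender-body rod drag
$S\,\eta\,L$ with $S_\parallel = 2\pi/\ln(L/d)$,
$S_\perp = 4\pi/\ln(L/d)$. The regime constants beyond these contracts are
the package's own calibration of the cited empirical forms; the tests pin
the limits, the branch boundary, and monotonicity rather than specific
interior values.

## A worked case study

```{r case-study}
sim <- run_case(simulation_config(n_species = 5, init_conc_uM = 5))
summary(sim)
```

Over 90 minutes only a small fraction of the 1600-mers associate (the
forward rate at micromolar loadings is slow), so concentrations drift
rather than swing; the effective viscosity tracks the 1600-mer
concentration downward and every species' diffusion bracket drifts
accordingly. The bounds stay within a factor ~2.3 band set by the
geometry ladder: the fastest value is the 1600-mer moving along its axis,
the slowest the largest species moving broadside.

```{r trends}
res <- as.data.frame(sim)
cor(res$eta_e_pa_s, res$F1600_uM, method = "spearman")
cor(res$eta_e_pa_s, res$F8000_uM, method = "spearman")
range(res$k_lower_F8000)
range(res$k_upper_F1600)
```

## What the synthetic DLS generator does and does not emulate

`generate_synthetic_dls()` perturbs a model diffusion series (by default
the lower-limit coefficient of the smallest species, closest to what DLS
reports for an associating suspension) with multiplicative lognormal noise
of chosen coefficient of variation, reproducibly under a seed. It emulates
instrument scatter only: real DLS traces additionally carry
intensity-weighting toward large particles, correlated drift, and
polydispersity artifacts that the generator deliberately omits. Passing
tests against these fixtures therefore validate the pipeline's plumbing
and noise calibration, not agreement with real instruments.

## Known limitations

* The effective-viscosity recipe is a weighted average; mixture rheology
  via stress tensors and solute-solute "mutual viscosity" interaction
  terms are out of scope, as are non-Newtonian effects.
* Only lateral association is modeled: no monomer-addition elongation,
  nucleation, or fibril maturation, and no stochastic (Gillespie)
  simulation.
* Rate constants are taken as given; fitting them to data is out of scope.
* The spatial reaction-diffusion problem that a concentration-dependent
  diffusion coefficient induces is not solved here.
* The model's absolute diffusion values at the case-study loadings sit
  above the published 1.7-2.4 x 10^-12 m^2/s band: at ~2% solute volume
  fraction the effective viscosity is only ~7% above water, and no
  averaging convention consistent with the model's own validated limits
  compresses the full upper/lower bracket of all species into a band that
  narrow (the geometric spread between the fastest and slowest bound is
  a factor ~2.3 at any instant). The package reports what the model
  computes; the trend structure, not the absolute band, is the validated
  content.
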