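---
title: "The NO-cGMP pathway model and its combination analysis"
author: "cgmpScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NO-cGMP pathway model and its combination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmpScreen)
```

## The model

Nitric oxide (NO) signals through soluble guanylyl cyclase (sGC): NO binds
the enzyme's heme, and the NO-sGC complex converts GTP to the second
messenger cGMP roughly 200-fold faster than free sGC does. Phosphodiesterase
(PDE) closes the loop by hydrolyzing cGMP to GMP. Oxidative stress attacks
the synthetic limb twice: hydrogen peroxide irreversibly inactivates free
sGC, and free NO radical is lost to oxidation.

`cgmpScreen` models this as a closed mass-action system of 12 species and 13
rate constants:

| reaction | constants | role |
|---|---|---|
| H2O2 + sGC -> sGC(ox) | k1 | oxidative inactivation of free sGC |
| NO + sGC <-> NO-sGC | k2, k3 | activation; k3 is the dissociation leak |
| sGC + GTP <-> sGC-GTP -> sGC + cGMP | k4, k5, k8 | basal synthesis |
| NO-sGC + GTP <-> NO-sGC-GTP -> NO-sGC + cGMP | k6, k7, k9 | activated synthesis (k9 = 200 k8) |
| cGMP + PDE <-> cGMP-PDE -> PDE + GMP | k10, k11, k12 | degradation |
| NO -> (lost) | k13 | oxidative loss of free NO |

All concentrations are micromolar, all times seconds; bimolecular constants
are 1/(uM s), unimolecular 1/s. The system is closed: the sGC moiety, the
guanine-nucleotide pool, and the PDE pool are each conserved along any
trajectory, and NO is conserved once the integrated k13 loss is added back.
The test suite asserts all four balances (relative drift below 1e-6) on 100
randomized parameter sets.

Two modeling choices deserve emphasis. NO enters as an initial bolus rather
than a sustained source: the NO synthesis and diffusion step is not resolved,
and the governing equation for NO contains no production term. And H2O2 is
consumed stoichiometrically by the sGC it oxidizes — at the standard 500 uM
challenge against sub-micromolar sGC it is effectively constant.

## Default parameters

The package ships a frozen default parameter set and initial state
(`defaultParameters()`, `defaultInitialState()`). These are calibrated
surrogates, not literature measurements: they were chosen, by a coarse grid
search refined by hand, to reproduce the dynamic signatures that
characterize this system, and then frozen:

* control cGMP rises abruptly to its peak within 40 s and is back at
  baseline (at most 10% of peak) well before 200 s;
* a 500 uM H2O2 challenge suppresses peak cGMP about 6-fold;
* the activity ratio k9/k8 is exactly 200;
* the four dominant single perturbations (10-fold inhibition under oxidant
  challenge) are k1, k3, k10, and k12;
* among k1, k3, k10, the NO-sGC dissociation rate k3 has the steepest 1-D
  dose response; and
* time-integrated cGMP increases in the order {k1,k3} < {k3,k10} <
  {k1,k3,k10}, with the triple the global optimum of the full 377-spec
  screen.

The resulting regime is mechanistically interpretable. Free NO decays fast
(k13 = 1.8/s) while bound NO is protected, and free sGC oxidizes fast under
the challenge while NO-bound sGC is protected. Inhibiting dissociation (k3)
therefore compounds three benefits at once — more flux to catalysis, longer
sGC survival, longer NO survival — which is what makes it the most
dose-sensitive knob. The PDE limb operates near its Michaelis regime
(Km = (k11 + k12)/k10 = 1.24 uM against sub-micromolar cGMP), so deep k10
inhibition is potent while shallow inhibition is partially buffered.

Defaults: k1 = 0.04, k2 = 8, k3 = 0.1, k4 = 5e-4, k5 = 0.01, k6 = 0.01,
k7 = 0.1, k8 = 0.05, k9 = 10, k10 = 2.5, k11 = 0.1, k12 = 3, k13 = 1.8;
initial NO = 0.5, sGC = 0.2, GTP = 50, PDE = 0.08 uM, everything else 0.

## Numerics

The ODEs are stiff in places (oxidation at 500 uM H2O2 is fast against
catalysis), so `simulatePathway()` uses deSolve's `lsoda` — a variable-order
solver that switches between Adams and BDF methods — with rtol 1e-8 and
atol 1e-10 uM. Output is evaluated on a uniform grid, 201 points over
[0, 200] s by default (1-s resolution). Undershoots below zero within
100 x atol are clamped to zero; anything lower aborts, since that indicates
genuine instability rather than tolerance-level noise. A fixed-step
fourth-order Runge-Kutta reference integrator (internal, dt = 1e-4 s)
cross-checks the adaptive solution on short horizons to a relative 1e-4 in
the tests.

Time-integrated cGMP (`integrateCGMP()`), the screening metric, is the
composite trapezoidal integral of the cGMP trace over [0, T], T = 200 s.
On the 1-s grid this is accurate to well under 1e-4 relative for the smooth
trajectories involved (verified against closed forms). Peak cGMP and peak
time are carried as secondary columns throughout.

Screen rankings sort by descending cGMP_T with ties broken lexicographically
by target set, making output byte-reproducible. Failed solves (none occur
with the shipped defaults) are retained with a status flag and a warning,
never silently dropped.

## The perturbation screen

A perturbation multiplies 1-3 distinct rate constants by ratios in (0, 1],
emulating concentration-dependent inhibitors; the headline screen applies a
uniform ratio of 0.1 to every member of every subset of sizes 1-3 of the 13
constants — 13 + 78 + 286 = 377 simulations under the oxidant condition.
Two normalizations are reported, against the unperturbed oxidant baseline
and (optionally) against the no-oxidant control, since either reference is
defensible for "relative cGMP_T".

Dose vectors for the combination analysis are 11 linearly spaced ratios
from 1.0 down to 0.1, 0.3, or 0.5 for single, paired, or triple
perturbations — shallower minima for larger combinations, mirroring the
dose-sparing rationale of combination therapy. The dose-sensitivity
comparison between k1, k3, and k10 is made at the matched minimum 0.5 (the
triple convention) on the cGMP_T span across the vector; this is the
package's operationalization of "most sensitive parameter", chosen because
it compares all three constants over a common, toxicity-relevant dose range.

## Bliss independence

Two readings of a Bliss null model are defensible for ratio-style
perturbations, and both are implemented in `blissPredict()`:

* `response-product` (default): standard Bliss independence on fractional
  effects, E_ij = E_i + E_j - E_i E_j. `blissComparison()` converts cGMP_T
  responses to fractional effects on the span between the unperturbed
  oxidant baseline and the no-oxidant control.
* `ratio-product`: the combined perturbation ratio as the literal product
  of the individual ratios.

The machinery is verified against a constructed null model
(`independentLossResponse()`) in which the cGMP deficit factorizes across
two non-interacting loss channels, making Bliss independence exact: the
observed-minus-predicted excess is zero to machine precision there. With
the calibrated defaults, all three headline pairs ({k1,k3}, {k1,k10},
{k3,k10}) at ratio 0.3 show positive excess — the combinations beat
independent action of their parts.

## Isobole classification

`classifyIsoboles()` works in the dose plane d = 1 - rho. Effect levels are
specified as fractions (default 25/50/75%) of the largest effect attainable
by *both* single agents — the smaller of the two axis maxima — so that
every extracted contour has intercepts on both dose axes, the classical
isobologram requirement. (Referencing levels to the joint maximum instead
would leave most contours without axis intercepts here, because the
combined effect dwarfs what either agent achieves alone.) Contours are
extracted by bilinear interpolation; each is summarized by a curvature
index: the signed area between the contour and the straight chord joining
its axis intercepts, normalized by the area of the triangle the chord forms
with the origin. |index| <= 0.05 is called additive; beyond that, bowing
toward the origin is synergistic and away is antagonistic. Three-axis
surfaces are classified on their three rho = 1 faces plus the main diagonal
plane (equal doses on the first two axes against the third).

The threshold and the index are the package's quantitative stand-in for a
visual straightness judgment; both synthetic oracles — an exactly
dose-additive surface and a potentiation surface — are recovered correctly,
and classifications are stable under grid refinement from 11 to 21 points
per axis for the pairwise surfaces.

A structural finding is worth stating plainly. With the calibrated
defaults, the three headline pairwise surfaces classify *antagonistic* by
this curvature rule (indices about -0.10 to -0.32), not additive, even
though the same pairs beat the Bliss prediction. Both observations follow
from the same cause: across these perturbation pairs, cGMP_T factorizes
approximately as a product of single-ratio responses (synthesis lifetime
times degradation rate, or oxidation pressure times dissociation
protection). A multiplicative response exceeds Bliss independence on the
effect scale, while its iso-effect contours are the hyperbolae
(1 - d1)(1 - d2) = K, which bow away from the origin — and contour geometry
is invariant to any monotone rescaling of the response, so no rate
recalibration can straighten them while preserving the multiplicative
mechanism. Loewe (dose-additivity) and Bliss (independence) verdicts simply
disagree for this system; users should read the two outputs as answering
different questions.

## The synthetic-data module

`sampleParameters()` draws each rate constant log-uniformly within a stated
number of decades of its default (k9 is re-derived as 200 k8, preserving
the activity ratio by construction); it exists to exercise the conservation
and solver properties across parameter space, not to represent biological
variability. `noisyTimecourse()` adds zero-mean Gaussian noise with SD
proportional to peak cGMP, a deliberately minimal stand-in for immunoassay
scatter: it is homoscedastic, uncorrelated in time, and unclamped (small
negative readings occur, as in background-subtracted assays). Passing tests
under this generator demonstrates numerical and statistical correctness of
the pipeline — not that the surrogate parameter set matches any particular
cell type's kinetics.

## Problem sizes

The shipped test and pipeline configurations use the 377-spec screen at the
standard 201-point grid, 11x11 pairwise surfaces (121 solves each, with one
21-point refinement at 441), one 11x11x11 triple surface (1331 solves) with
a 7-point reduced companion, 100 randomized parameter sets for conservation
checks, and 200 Monte-Carlo noise replicates — sizes chosen so a complete
run finishes in minutes on a single core while still exercising every code
path at the conventions described above.

## Known limitations

* The default parameters are calibrated surrogates; absolute concentrations
  and times should not be read as measurements of any specific cell system.
* NO is a bolus; sustained NO delivery (donor pharmacokinetics) is out of
  scope.
* The model is deterministic mass-action in a well-mixed compartment: no
  spatial NO transport, no stochastic kinetics, no explicit redox couple
  for sGC re-reduction.
* Hard-threshold classification flips labels when a curvature index sits on
  the 0.05 boundary; the index itself converges under grid refinement and
  is the quantity to compare across runs.
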