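---
title: "Models and methods for single-turnover RISC slicing kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-turnover RISC slicing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicekin)
```

## The measurement and the model

A single-turnover slicing assay follows the cleavage of a trace radiolabeled
target RNA (0.05 nM) by an excess of RISC (an Argonaute2-guide complex) at
2, 5, and 10 nM total. Because the enzyme is in large excess, each target
molecule is bound and sliced at most once, so target dissociation and
product release do not influence the observed rates; the progress curve is
governed by the association rate constant `kon` (/nM/s) and the slicing rate
constant `kslice` (/s) alone.

Real RISC preparations are heterogeneous: a fraction `Fa` of complexes is
functionally intact, while the remainder binds the target normally but
slices it orders of magnitude more slowly, producing a shallow second
kinetic phase with rate constant `kphase2`. The package models this with a
two-population mass-action scheme,

$$
\begin{aligned}
E + S &\xrightarrow{k_{on}} ES \xrightarrow{k_{slice}} E + P \\
E' + S &\xrightarrow{k_{on}} E'S \xrightarrow{k_{phase2}} E' + P
\end{aligned}
$$

with initial conditions $E = F_a E_{all}$, $E' = (1-F_a)E_{all}$, $S = S_T$,
and all complexes and product zero. The observable is the fraction of target
sliced, $F_{sliced} = P / (P + S + ES + E'S)$. Three conservation laws
($S+ES+E'S+P$, $E+ES$, $E'+E'S$) hold exactly and are enforced in tests to
1e-8 relative.

Binding is irreversible in this scheme. Under enzyme excess the first
binding partner decides a target molecule's fate, so as $t \to \infty$ with
`kphase2 = 0` the sliced fraction converges to `Fa` — a useful structural
check that the test suite exercises.

## Two-stage fitting

Fitting follows a two-stage design. The **guess stage** fits a
pseudo-steady-state closed form,

$$
F_{sliced} = F_a\!\left(1 - e^{-t\,/\,(1/(k_{on}E_{all}) + 1/k_{slice})}\right)
 + (1-F_a)\!\left(1 - e^{-k_{phase2}t}\right),
$$

jointly across the concentration series by Levenberg-Marquardt least
squares. The first-phase timescale is the sum of the binding time
$1/(k_{on}E_{all})$ and the slicing time $1/k_{slice}$, which is what makes
the dilution series informative: only the binding term moves with
$E_{all}$, so measuring at several concentrations disentangles `kon` from
`kslice`. Initializations and bounds are the assay presets: `kon` starts at
0.02 /nM/s in (1e-6, 0.1); `kslice` at 0.0167 /s, or 1.67e-5 /s when the
final-time sliced fraction is below 0.3 (very slow reactions); `kphase2` at
3.33e-6 /s in (1.67e-6, 1.67e-4); `Fa` at 0.95 x the maximum observed
fraction, or 0.85 when the plateau is unreached, in (0.75, 0.999). If the
regression fails (degenerate data, e.g. all-zero traces), the initial
values are returned with `Fa` set to 0.85.

The **ODE stage** refines these guesses against the full mass-action model,
minimizing the *total absolute deviation* (L1) between observed and
predicted fractions over all points. Rate constants are optimized as log10
values; `Fa` is box-bounded in natural scale at (0.6, 1.0); `kon` is capped
at the diffusion limit 0.1 /nM/s; `kphase2` at (1.67e-6, 3.33e-3) /s
(detection limits of the longest assays); `kslice`, unbounded above in
principle, is capped at 1e2 /s for numerical stability, far above any
observed rate.

### Numerical choices

* **Solver.** The stiff backward-differentiation formula (`deSolve`'s
  `lsode`, `mf = 22`) with rtol 1e-8 and atol 1e-10 nM, because rate
  constants span six orders of magnitude. The right-hand side is compiled C,
  and all conditions of a dataset are stacked into one block-diagonal system
  so each objective evaluation is a single solver call. Concentrations that
  undershoot zero by less than 100 x atol (solver roundoff) are clamped;
  anything worse raises an error. Simulation output is validated against an
  independent fixed-grid Runge-Kutta integrator and, in the excess-enzyme
  single-population limit, against the sequential-reaction closed form. Note
  that the closed form itself carries an $O(S_T/E_{all})$ depletion error —
  at 100 x excess it differs from the true solution by ~3e-4, which is model
  structure, not solver error; limit tests therefore use 1000 x excess.
* **L1 via a smooth surrogate.** The absolute-deviation objective is
  optimized through pseudo-Huber-transformed residuals (delta = 1e-4, far
  below the typical 0.02 residual scale, so effectively L1 everywhere that
  matters) fed to a bounded Levenberg-Marquardt engine (`minpack.lm`). The
  loss is exposed (`loss = "l2"`) for sensitivity checks. Because LM on this
  surrogate can hit its iteration cap while standing still, a short warm
  restart verifies stationarity before a fit is declared unconverged.
* **Multistart.** The L1 surface is bimodal when the plateau and the second
  phase are weakly resolved: one basin has high `Fa` with `kphase2` at its
  floor, the other low `Fa` with fast `kphase2`. The ODE stage therefore
  runs from the guess plus two deterministic starts bracketing that axis and
  keeps the lowest objective.
* **Determinism.** Residual vectors are assembled in a canonical order
  (sorted by concentration, replicate, time), so estimates do not depend on
  the order in which time courses or points were supplied.

### Confidence intervals

The original analysis reports intervals "from model fitting" without naming
a construction, so the method here is the package's own choice: a residual
bootstrap. Residuals are resampled with replacement within each time course,
inflated by $\sqrt{n/(n-p)}$ to restore the variance absorbed by the $p$
fitted parameters, added to the fitted curve (clipped to [0, 1]), and the
model is refit warm-started from the point estimate. Intervals are *basic*
(reflected) bootstrap intervals computed on the log scale for rate
constants: in pilot simulations plain percentile intervals covered the true
`kslice` in only ~60% of nominal-95% cases because resampled estimates
inherit the estimator's convexity bias, which reflection corrects (coverage
~90% in the same pilot). Warm-starting keeps every draw in the basin of the
reported optimum; refits use slightly relaxed solver and convergence
tolerances (rtol 1e-6, ftol 1e-6), which changes draw spread by under 5%
at a third of the cost. Fixed parameters carry no interval.

### Fallback constraints

Three constrained refits mirror how degenerate designs are handled in
practice, applied iteratively (a refit can expose the next trigger):

* **`kon` at the diffusion limit.** When binding is much faster than
  slicing, the data carry no information about `kon`. Triggers: the
  bootstrap upper bound within 5% of 0.1 /nM/s, an interval spanning more
  than two decades, or — because warm-started draws cannot spread along a
  flat ridge — a deterministic profile check: if refitting with `kon` pinned
  at 0.1 raises the objective by less than 5%, binding speed is declared
  unresolved and the pin is kept.
* **`kphase2 = 0`.** When sampling ends before the second phase is visible
  (interval floor at 1.67e-6 /s, or the longest time point shorter than
  $1/(10\,k_{phase2})$), the defective-population rate is set to zero.
* **`Fa = 0.85`.** When the plateau is unreached (maximum observed fraction
  below 0.75), the amplitude cannot be estimated and is fixed at 0.85, the
  value used for such reactions in the original protocol.

## Active-stock titration

RISC preparations quantified without a radiolabeled guide are titrated
against 1-2 nM radiolabeled target and the bound fraction follows the
ligand-depletion (quadratic) isotherm

$$
F_{bound} = F_{max}\,
\frac{(s + T + K_D) - \sqrt{(s + T + K_D)^2 - 4 s T}}{2T},
\qquad s = [\mathrm{stock}] \cdot DF .
$$

Presets match the two guides: for miR-200b, stock in (0, 1e6) pM starting
at 1e5, $K_D$ in (10^0.5, 10^2.5) pM starting at 10^1.5 (log scale), and
$F_{max}$ fixed at 1 with target at 1000 pM; for let-7a, stock in (0, 2e6),
$K_D$ in (1e-10, 1e10) (log scale), $F_{max}$ free starting at 0.9, target
2000 pM. The quadratic prediction is validated against a root-finding
equilibrium solver and converges to the hyperbolic isotherm when
$T \ll K_D$. In the depletion-dominated regime the stock/$K_D$ surface has
a genuine local minimum (a pilot fit from the printed start converged to
(84,000 pM, 316 pM) instead of the generating (50,000 pM, 30 pM)), so the
preset start is supplemented by a deterministic restart ladder and the best
fit kept. The discriminant is clamped at zero within 1e-9 relative to
absorb floating-point loss at the stoichiometric corner.

Radiolabeled-guide preparations are quantified directly as
`duplex_conc * signal_risc / signal_duplex` against a duplex standard.

## Dissociation kinetics

Cold-chase filter-binding traces follow
$F_{bound}(t) = A e^{-k_{off} t} + B$, fit by least squares with `koff` in
log space (initialized at $e^{0.2}$ = 1.22 /s as in the protocol), `A` at
0.75 in (0, 1), `B` at 0.05 in (0, 1), at most 1000 iterations. When the
decay timescale is orders of magnitude slower than the 1.22 /s start the
exponential gradient vanishes at the start and LM stalls there, so the
printed start is supplemented by restarts at data-timescale rates
($1/t$ at several quantiles). Flat traces are flagged non-identifiable
(`A` driven to 0) rather than failing; unconverged fits report the initial
values with a non-converged flag.

## Fold changes

Condition comparisons (mutant vs wildtype; mismatched vs perfectly paired
target) are ratios of rate-constant point estimates. Interval: because the
bootstrap draws of the two fits are independent, the ratio distribution is
their convolution, computed exactly as all pairwise log-ratios (falling
back to random pairing under a seed only for very large draw sets); the
log-ratio quantiles are reflected around the point log-ratio (basic
interval) and exponentiated — intervals are asymmetric, as expected for
positive rates. A ratio whose interval includes 1 is flagged, mirroring the
convention of graying out non-significant comparisons; no further
hypothesis testing is attempted. A parameter fixed by a fallback constraint
in either fit cannot be compared, by design.

## Synthetic data: what it does and does not emulate

`generate_slicing_dataset()` reproduces the assay design — 0.05 nM target,
RISC at 2/5/10 nM, 12 log-spaced times from the fastest binding timescale
$1/(k_{on}\min E_{all})$ to five slicing lifetimes — and adds additive
Gaussian noise on the fraction scale (default sd 0.02, clipped to [0, 1]),
the simplest model consistent with gel-band quantification error.
`generate_titration()` and `generate_dissociation()` do the same for their
assays (titration noise default 0.03). Ground truth and the noise seed ride
along as attributes, which is what the recovery tests close their loop on.

Not emulated: heteroscedastic or correlated quantification error, gel band
overlap, radioactive decay corrections, pipetting error in the dilution
series, or time-stamp uncertainty. Passing recovery tests therefore
demonstrate correctness of the estimation machinery under a known noise
model, not robustness to every artifact of real gel data.

## Problem sizes used in validation

The recovery and coverage studies use the study design (3 concentrations x
12 time points), 20 replicate datasets for median-error statements, 50
replicate experiments for interval-coverage statements (200 bootstrap
resamples each for single-parameter coverage; 50 per fit for the
fold-change coverage study), and triplicate 16-point chases for the 20x
dissociation comparison. These sizes give the coverage estimates a Monte
Carlo standard error of ~4-5 percentage points, comfortably inside the
tolerances asserted.

## Known limitations

* `kphase2` is reported but rarely well determined by 1000-s designs; its
  interval should be read together with the `kphase2 = 0` fallback flag.
* The L1/pseudo-Huber objective is not a likelihood; intervals are
  resampling-based and inherit the usual small-sample caveats of the
  bootstrap (the coverage studies quantify this under the stated noise
  model).
* Joint fitting across concentrations assumes one shared parameter set per
  dataset; guide- or target-specific differences must be handled as
  separate datasets compared through `fold_change()`.
* No multi-turnover, product-release, or biphasic-dissociation models.
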