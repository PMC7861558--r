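---
title: "Modeling signal-induced cell-polarity switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling signal-induced cell-polarity switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polswitch)
```

## The model

Rod-shaped bacteria such as *Myxococcus xanthus* mark their leading pole
with a polarity marker (MglA, here `A`) whose localization is controlled by
an antagonist (MglB, `B`) and a recruitment factor (RomR, `R`). Because
cytoplasmic diffusion is fast compared with the polarity kinetics (the
mixing time `L^2 / 2D` of a 6 um cell at `D = 10 um^2/s` is
`r mixing_timescale(6, 10)` s), the cell is treated as three well-mixed
compartments: pole 1, pole 2 and the cytoplasm. Each protein's total is
normalized to one, so the state is the 8 polar abundances
`(A1, A2, R1, R2, B1, B2, X1, X2)` and cytoplasmic pools are implicit.

At each pole `i`:

* `R` binds at rate `k_R`, is recruited by polar `B` at `k_bR`, unbinds at
  `k_r`, and recruits `A` at `k_rA`;
* `A` unbinds spontaneously at `k_a` and is displaced by `B` at `k_ba B_i^2`;
* `B` binds at `k_B`, self-recruits at `k_bB`, is displaced by `A` at
  `k_ab A_i B_i^2`, and unbinds at a *saturating* rate
  `k_b k_M B_i / (k_M + B_i)` — unbinding of `B` slows as polar `B`
  accumulates, with `k_M` the characteristic abundance of that feedback.
  (The saturating form follows the verbal description of the interaction;
  the typeset source of this term is ambiguous, which is flagged here
  deliberately.)

Mutual `A`–`B` antagonism plus `B` self-recruitment make the unsignaled
model bistable: two stable fixed points with the marker enriched at either
pole, mirror images under pole exchange, separated by a separatrix through
the unstable symmetric configuration. Polarity is measured by
`omega_A = (A1 - A2) / (A1 + A2)`; a reversal is a sign change of
`omega_A`.

A signaling protein `X` (FrzX-like) conveys a *non-directional* pulse: its
total `X_t` jumps to `X_max` for a duration `tau` (optionally with gradual
exponential edges of rate `lambda`). Polar `B` recruits cytoplasmic `X` at
`k_X`; polar `X` unbinds at `k_x`. Polar `X_i` regulates exactly one of the
11 core constants, multiplicatively: `k (1 + X_i)` (enhancing) or
`k (1 - X_i)` floored at zero (repressive, since `X_i` can exceed 1).
Eleven rates times two signs give the 22 candidate regulation scenarios of
`enumerate_scenarios()`.

## Base parameters and fixtures

`base_parameters()` returns the reference constants
(`k_rA = 400, k_a = 2, k_ba = 400, k_B = 2, k_bB = 30, k_b = 2.8,
k_M = 0.3, k_ab = 15, k_R = 0.1, k_bR = 1.5, k_r = 0.4, k_X = 20,
k_x = 3`, units min^-1 except the dimensionless `k_M`).
`perturbed_parameters()` multiplies every constant by an independent
uniform draw on [0.5, 1.5], the robustness protocol used throughout;
published perturbed sets can be reproduced exactly by injecting their
multipliers.

## The switching experiment

`run_switch_experiment()` implements the three-phase protocol. Phase 1
relaxes the no-signal model to a polarized fixed point. The symmetric
manifold is dynamically invariant, so relaxation needs a seed asymmetry:
each species starts uniformly distributed (1/3 per compartment) with an
extra 0.01 of `B` at one pole, a choice the protocol leaves open; by
pole-exchange symmetry the experiment is orientation-independent, and all
runs start polarized toward pole 1 by convention. Phase 2 applies the
pulse on `[0, tau)`; phase 3 runs signal-free until `t_end = 30` min,
long enough to re-relax. The experiment is a *switch* when `omega_A`
changes sign between `t = 0` and `t_end`.

Integration uses an adaptive stiff-capable solver (lsoda, relative
tolerance 1e-8, absolute 1e-10), piecewise across signal edges. At a
falling step edge the total `X_t` drops instantly, so the chained state is
projected onto the new bound (polar `X` rescaled onto `X1 + X2 <= X_t`);
this matches the stochastic model's clipping and keeps the N -> infinity
limit of the Langevin engine on the ODE solution. Switch events are sign
changes of `A1 - A2` between samples (0.01-min sampling by default), with
grid-exact zeros attached to the preceding sign and event times linearly
interpolated. Raw crossings are deliberately noise-sensitive near the
symmetric state; an optional hysteresis band (off by default) is provided
for exploratory use.

## Stochastic model

The Langevin extension adds to each equation a noise term
`sqrt(f) eta`, where `f` is the sum of the absolute fluxes of that
equation (multiplicative noise) or the same sums at the uniform reference
state `(1/3, ..., X_t/3)` (white noise), and `eta` are independent
Gaussian noises of spectral density `1/N`. `N` is an effective copy
number: the deterministic model is recovered as `N` grows. Integration is
Euler-Maruyama with `dt = 1e-4` min; after every step components are
floored at zero and polar sums exceeding a species' total are rescaled
proportionally onto the bound (proportional rescaling avoids biasing
either pole; the constraint itself is part of the model, its projection
is a design choice). `sqrt(f) = 0` on a dead channel. The inner loop is
compiled (C++); each realization draws from a substream keyed by
`(seed, realization)`, so ensembles are reproducible and independent of
evaluation order. Phase 1 of the stochastic protocol is itself stochastic:
ensembles equilibrate for a 5-min signal-free burn-in before `t = 0`, and
each realization's own `omega_A` sign at `t = 0` is the reference for the
switch comparison.

The engine is verified against Monte-Carlo moment oracles (one-step mean
`dt d(x)`, variance `dt f(x)/N`, vanishing skewness) and against the ODE
solution at `N = 1e10`.

## Classifying regimes and mechanisms

`classify_persistent_signal()` applies the signal for the whole run
(`T_long = 100` min), discards the first half as transient, and labels the
dynamics *symmetric* if `|omega_A| < 0.01` through the final tenth of the
window, *oscillatory* if `omega_A` keeps alternating sign (>= 3 sign
changes with peak `|omega_A| > 0.05`), and *polarized* if a steady nonzero
`omega_A` remains. The thresholds are this package's choices: the source
protocol names the three classes but no cutoffs. The symmetric check runs
first so that a slowly decaying spiral is not mistaken for a limit cycle.

`classify_mechanism()` then assigns every deterministic switch one of four
labels:

* **transient oscillator** — oscillatory during the signal; the final
  polarity depends on the oscillation phase at removal, so switching
  alternates in `tau` with band width equal to half the limit-cycle
  period;
* **reset** — symmetric during the signal: polarity is erased and chosen
  anew on removal (deterministically by the tiny remnant asymmetry;
  with probability 1/2 under noise);
* **prime-release** — bistable during the signal with the fixed point
  displaced across the old separatrix; the reversal starts only after
  removal (first `omega_A` crossing at `t >= tau`);
* **push** — bistable with the separatrix displaced across the state; the
  reversal starts during the signal (first crossing at `t < tau`).

The push/prime-release timing rule operationalizes "switch during" versus
"switch after removal" via the interpolated first crossing. Representative
cells for the four mechanisms are located by `find_mechanism_representatives()`
from deterministic scans of three regulation families (`k_ab` enhanced:
banded oscillatory regime at moderate amplitude and a symmetric reset
regime at high amplitude; `k_ab` repressed: solid prime-release regime;
`k_rA` slightly enhanced: a narrow push band below the oscillation onset
near `X_max = 0.18`). The scan windows are package defaults found by
exploratory scanning — the source marks its example signals only
graphically, so the located values are this package's own. Reset
representatives prefer the longest labeled duration, since full erasure of
polarity is the mechanism's defining feature.

With the base parameters the located representatives are `k_ab+`
(`X_max = 4, tau = 2`) for the transient oscillator, `k_ab+`
(`X_max = 80, tau = 6`) for reset, `k_ab-` (`X_max = 4, tau = 8`) for
prime-release, and `k_rA+` (`X_max = 0.18, tau = 15`) for push.

## Phase-space machinery

`find_fixed_points()` runs a damped Newton iteration (finite-difference
Jacobian) from 20 random valid states plus the symmetric state and the two
relaxed polarized states, merges roots at 1e-5 and classifies stability by
Jacobian eigenvalues; reported residuals are below 1e-8.
`basin_label()` integrates signal-free until the trajectory reaches a
stable fixed point. `estimate_separatrix_projection()` samples the primed
ensemble at `t = tau` (reference protocol `N = 1e3`), labels each endpoint
by its basin, and fits a default linear discriminant per 2D projection of
the pole-difference coordinates `(A1-A2, B1-B2, R1-R2)`; the projections
use these difference coordinates with the symmetric configuration at the
origin, and no nonlinear boundary is attempted. The evolving state is
8-dimensional (polar abundances only; a ninth dimension sometimes quoted
for this phase space has no evolving coordinate here, a discrepancy noted
deliberately). `extract_limit_cycle()` returns one period of the
persistent-signal cycle, delimited by upward `omega_A` crossings, and
basin-labels points along it after signal removal; the labels partition the
cycle into the two arcs on either side of the no-signal separatrix.

## Spectra and coherence resonance

`welch_psd()` is an averaged-periodogram estimator (Hann window, 50%
overlap); no installed package provides one, so it is implemented on the
FFT directly and validated against Parseval's identity and analytic
cases. Segments are *not* demeaned by default: the coherence metric of
`coherence_metric()` — maximal power density over nonzero frequencies
relative to the power at zero frequency — is defined against the total
zero-frequency power, and `A1 - A2` has mean about 0.78 in a polarized
cell. With demeaning the DC term would vanish and the ratio would lose its
meaning; `detrend = "constant"` remains available for fluctuation spectra.

Without any signal, noise alone drives polarity flips. At weak noise
(large `N`) flips are absent over hundreds of minutes and the spectrum is
dominated by the DC peak. Near `N ~ 10^1.5` the activation time becomes
comparable to the relaxation time and the dynamics is quasi-oscillatory:
the PSD of `A1 - A2` develops a finite-frequency peak and the coherence
metric passes through an interior maximum — coherence resonance. A useful
independent check implemented in the tests: the polarized fixed point has
an underdamped eigenpair (about `-0.29 +/- 0.56i` min^-1 at base
parameters), and the small-noise fluctuation spectrum peaks at its
eigenfrequency `Im(lambda)/2pi ~ 0.089` cycles/min.

## Numerical choices and desk-scale defaults

* Solver tolerances 1e-8/1e-10; fixed-point residual threshold 1e-8;
  relaxation time cap 1000 min.
* Euler-Maruyama step 1e-4 min; event sampling 0.01 min.
* Default scan grids are configurable; the bundled windows (above) are
  exploratory defaults chosen to bracket banded and solid regimes of the
  base parameter set.
* Spectral runs default to traces of a few thousand minutes with
  2^13-2^14-sample segments, roughly tenfold shorter than the reference
  protocol's 50000-min traces; segment counts stay >= 5 so the averaged
  periodogram remains consistent. Ensemble sizes of 300 realizations give
  binomial standard errors below 0.03 on probabilities near 0.5.
* Division by `k_M + B_i` is guarded for the degenerate `k_M + B_i = 0`
  (reachable only if `k_M` is regulated to zero while a pole is empty);
  `omega` at a fully depleted pole is reported as 0 with a degenerate
  flag — the dynamics never reaches that state from valid initial
  conditions.

## What the simulations do and do not show

The package's generators emulate the study conditions exactly: the
three-compartment idealization, unit totals, step or exponential-edge
pulses, and state-dependent Gaussian noise. They do not emulate spatially
resolved transport (no PDE variant; fast mixing is assumed), molecular
discreteness (no exact jump process is defined by the rate equations, so
the Langevin form is the model, not an approximation of a master
equation), or receptor-level signal generation (the pulse is prescribed,
not produced by an upstream pathway). Passing tests therefore certify the
dynamics of this idealized circuit, not quantitative behavior of real
cells.

One quantitative caveat is documented openly: with the equations
implemented exactly as printed, all qualitative stochastic phenomena
reproduce (noise-robustness ordering of the mechanisms, damped
oscillations of the switching probability around 0.5, the reset
coin-flip, coherence resonance), but the noise level at which they occur
sits two- to threefold higher in noise variance (about 0.3-0.5 decades
lower in `N`) than the reference account reports. The affected end-to-end
checks in `tests/testthat/test-acceptance.R` assert the reference values
and are expected to fail, which is intentional: they document the
discrepancy rather than hide it. The engine's own moment oracles pass at
tight tolerance, so the shift is not an integration artifact.
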