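---
title: "Response-surface optimization of emulgel formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization of emulgel formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emulgelopt)
library(dplyr)
```

`emulgelopt` implements the computational side of a formulation-optimization
study of a thermoresponsive emulgel: a poloxamer 407 hydrogel carrying an
oil-in-water emulsion and 1 % ciclopirox olamine, with mineral oil and
polysorbate 80 as the design factors. This vignette is the package's account
of the underlying models, the tunable parameters and the design choices
made where several defensible options existed.

## The experimental design

Two factors span the design region: mineral oil 10–50 % w/w and
polysorbate 80 0–10 % w/w. Coded levels `A = (X1 − 30)/20` and
`B = (X2 − 5)/5` place the centre at 0 and the range limits at ±1, which
makes polynomial coefficients directly comparable across factors.

The design is a face-centred central composite design (axial distance
α = 1): 2² factorial corners, 4 axial points on the face centres and a
centre point — nine runs. The source study never states α, but its printed
levels are only −1/0/+1, and a face-centred CCD is the unique CCD consistent
with that (equivalently a 3² factorial without replicated centres). No centre
replicates are generated by default, matching the nine printed runs;
`ccd_design(space, center_points = k)` adds them for users who need a
pure-error estimate.

Each run is completed into a recipe by `complete_formulation()`:
ciclopirox olamine fixed at 1 %, poloxamer 407 following the linear rule
`poloxamer = 25 − 0.25 · oil` (inferred from the printed compositions:
22.5/17.5/12.5 % at 10/30/50 % oil, and exposed as a configurable
intercept/slope pair), purified water as balance to 100 %. Components are
validated non-negative and the total is checked to 1e-9.

```{r design}
emulgel_design() |> select(run_id, mineral_oil, polysorbate_80,
                           poloxamer_407, purified_water)
```

## Polynomial models and their diagnostics

For each response, `rsm_fit()` solves ordinary least squares on the coded
model matrix for one of three families: linear (`1, A, B`), two-factor
interaction (`+ AB`) and quadratic (`+ A², B²`). Replicate tables fit at
replicate level (every measurement a row). The actual-factor coefficients
are produced by exact binomial expansion of the affine substitution, never
by refitting, so the two parameterizations agree at any point to machine
precision — a property tested at 1000 random points.

Diagnostics follow design-of-experiments convention:

- `PRESS = Σ (e_i / (1 − h_ii))²`, the leave-one-out prediction error via
  hat diagonals, with `pred R² = 1 − PRESS/SST`. The shortcut is tested to
  1e-10 against explicit n-refit leave-one-out.
- `adeq precision = range(ŷ) / sqrt(p · MSE / n)` over the design points,
  the signal-to-noise measure conventionally required to exceed 4.
- Per-term partial-F tests (reported as t statistics; identical p-values).

Model adequacy uses the study's three rules: model p < 0.05,
adj R² − pred R² < 0.2, adeq precision > 4 — all exposed as `run_config()`
thresholds.

### Family selection

The study's narrative selection rule ("the lowest-order adequate model")
turns out to be indeterminate on this design: for the strongly curved
responses the linear fit *also* passes all three adequacy rules, while
picking whichever adequate family has the best predicted R² upgrades truly
linear responses to quadratic in a fifth of simulated worlds (spurious
terms barely hurt PRESS at replicate-level n). `select_model()` therefore
follows the convention of DoE software: the sequential model sum of squares
suggests the highest family whose block of added terms is jointly
significant by an incremental F-test, and the suggestion is then validated
against the three adequacy rules. The suggestion level defaults to
`alpha_seq = 0.01`: with two candidate blocks above linear, a 5 % level
would allow a ~10 % spurious-upgrade rate, whereas 1 % bounds it near 2 %;
genuine curvature in this system has block p-values below 1e-6, so any
threshold in between behaves identically on signal.

### Term pruning

`prune_terms()` removes, one at a time with refits, terms with p above the
retention threshold (default 0.10), never touching the intercept or a main
effect that supports a retained interaction or square (model hierarchy). A
single-pass variant is available. Note a statistical consequence of the
0.10 threshold: a null term survives pruning with probability near 0.10, so
with four null terms the fully pruned form is reached in about 0.9⁴ ≈ 66 %
of replicated worlds — the tests assert that rate, not perfection.

## Desirability optimization

Each response enters through a Derringer–Suich transform: for maximization
`d = clip((y − L)/(U − L))^w`, mirrored for minimization, a two-sided ramp
for target goals and an indicator for in-range goals. The composite
desirability is the importance-weighted geometric mean, zero whenever any
individual desirability is zero.

The study states neither its bounds `(L, U)` nor weights. Defaults here:
weights and importances 1, and bounds at the per-response extremes of model
predictions over the design runs (the usual software default of the
observed response range). Because those inputs are unrecoverable, the
published optimum — 38.27 % oil, 6.56 % polysorbate, D = 0.646 — is treated
as a soft target: with default bounds the optimizer lands at 39.7 % / 6.1 %
with D = 0.614, within three percentage points and ΔD < 0.04 of the printed
values, and the discrepancy is reported rather than hidden.

`optimize_desirability()` evaluates a dense grid (0.05 % steps) over the
factor box, then refines from the best cell and from seeded random starts
with bounded quasi-Newton iterations; ties on flat ridges break toward the
design centre, making results deterministic given the seed. On concave
single-response problems the optimizer matches closed-form stationary
points to 0.01 %.

## Release kinetics and rheology

The release test geometry follows the study: 50 mL acceptor medium, 1.33 cm²
diffusion area, hourly sampling for 6 h, 10 mg dose (1.0 g of a 1 %
formulation). The withdrawn sample volume is never stated; the default is
1 mL, configurable. Because each withdrawal removes drug, raw
concentrations are corrected by the running sum
`C*_n = C_n + (V_s/V) Σ_{i<n} C_i`; the correction exactly inverts the
simulated withdrawal process and vanishes at `V_s = 0`.

Release flux is defined as the corrected cumulative amount at the final
time point divided by the diffusion area (mg/cm²) — consistent with the
study's printed flux sitting well below the mass-conservation ceiling
dose/area = 7.52 mg/cm². A slope-based alternative (mg/cm²/h through the
origin) sits behind `release_flux(method = "slope")`.

First-order kinetics is fitted as the saturating exponential
`Q(t) = Q∞(1 − e^{−kt})` with `Q∞` bounded by the dose, by
Levenberg–Marquardt least squares from several starts (the best SSE wins).
The saturating form is preferred over log-linearization because late points
near the plateau make the log transform ill-conditioned; the linearized fit
is kept as a test oracle. Zero-order and Higuchi models are linear fits
through the origin.

Sol–gel transition: poloxamer systems gel on warming, so a downward
temperature ramp shows a step in storage modulus G′. `detect_sol_gel()`
takes the adjacent-pair window with maximal |ΔG′/ΔT| and reports its
midpoint, mirroring how a single transition temperature is quoted from an
interval criterion. On the default 1 °C ramp the midpoint carries an
inherent ±0.5 °C quantization; flat or exactly linear sweeps (every window
tied) raise a "no transition" error. Detection is invariant to the ramp
direction.

## Nonparametric tests

Spearman's rho is the Pearson correlation of midranks (tie-safe by
construction), with an exact permutation p-value (all n! orderings) below
n = 10 and the t approximation above. Mann–Whitney U comes from midrank
sums; the p-value is exact by enumeration for untied pooled samples of at
most 12, otherwise a tie-corrected normal approximation without continuity
correction. Kruskal–Wallis uses the tie-corrected H with a chi-square
reference. All tests are two-sided; all match enumeration oracles exactly
on small samples and hold the 0.05 level within [0.03, 0.07] in null
simulations. One caveat carried in the documentation: correlations printed
in the source study were computed on replicate-level data that is not
published, so rank correlations on the nine run means approach but do not
equal them (e.g. polysorbate vs droplet size: −0.949 on means vs −0.910
printed).

## The synthetic-data generator

The generator exists so every downstream stage has a printed ground truth:
its default generating models are the six published actual-factor
equations, and every acceptance check runs against data it produces.

- **Replicate responses**: prediction + additive Gaussian noise per
  replicate. Droplet size uses the published replicate SD scale (0.02 µm)
  and 5 replicates per run (repeated laser-diffraction measurements);
  other responses use 3 replicates and SDs chosen once at the 1–3 %
  relative error typical of the instrument class: pH 0.02, transition
  temperature 0.3 °C, flux 0.04 mg/cm², firmness 0.08 N, work of shear
  0.12 N·s.
- **Release profiles**: the true released mass follows the stretched
  exponential `Q(t) = Q∞(1 − e^{−(kt)^s})` with default shape s = 0.72 and
  1 % multiplicative measurement noise. The stretching is deliberate: real
  semi-solid release deviates systematically from ideal first-order
  kinetics — the study's own first-order R² band (0.9615–0.9908, never 1)
  says so — and white noise alone cannot reproduce that band reliably
  (residual sums of squares would scatter as a 4-df chi-square). With the
  calibrated defaults, ~98 % of simulated profiles land in the band.
  Per-run releasable amounts are set so the 6-h flux matches the flux
  equation's prediction at `k = 0.4 h⁻¹`.
- **Rheology sweeps**: a logistic step in G′ (sol plateau 10 Pa, gel
  plateau 10⁴ Pa, width 1.2 °C) centred on the transition model's per-run
  prediction, sampled on the 40 → 0 °C, 1 °C/min ramp.
- **Droplet percentiles**: lognormal quantiles (D10/D50/D90) with small
  multiplicative measurement error, summarized as means and SDs in the
  published layout.

All generators are pure functions of their arguments and a seed. What
passing tests on these worlds do *not* show: real emulgels have run-to-run
formulation error, correlated replicate structure, instrument drift and
model misspecification beyond the stretched-exponential release; parameter
recovery and family-selection rates measured here are upper bounds on what
real data would give.

## Numerical choices and problem sizes

- Least squares via QR; rank deficiency aborts with the collinear terms
  named rather than silently dropping them.
- Reparameterization between coded and actual factors is symbolic
  (binomial expansion with collected coefficients), an involution to 1e-9.
- Report rounding is half-away-from-zero (`round_half_up()`), matching how
  formulation tables are conventionally printed.
- Simulation studies in the test suite use 100–200 seeded worlds for
  recovery/selection rates and 2000 null draws for test-level checks;
  coverage assertions are per coefficient (nominal 95 % CIs asserted to
  cover ≥ 90 % of worlds).

## Known limitations

- Only rectangular factor regions are searched; the implicit mixture
  constraint (water as balance) is reported, not optimized over.
- No lack-of-fit F-test: the nine-run design has no replicated runs, so
  residual MSE absorbs any pure error.
- The published optimum cannot be reproduced exactly because the
  desirability bounds behind it are unpublished; the package reports its
  own optimum under documented defaults instead.
- Exact permutation p-values are enumerative (n! below 10) and deliberately
  capped at small n.
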