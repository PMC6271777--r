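---
title: "Analysing Langmuir monolayer isotherms with monolayr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Langmuir monolayer isotherms with monolayr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monolayr)
```

## The measurement and the model

A Langmuir film balance compresses a one-molecule-thick phospholipid film at
the air–water interface while recording the surface pressure
$\pi = \gamma_0 - \gamma$ (mN/m) and, with a vibrating-plate electrode, the
surface potential $\Delta\psi$ (mV), both against the area per molecule $A$
(Å²/molecule). Studies of how subphase-dissolved compounds perturb membrane
lipids summarise each compression run by a handful of landmarks:

- the **lift-off area**, where $\pi$ first rises detectably above the
  clean-surface baseline — larger lift-off means the film occupies more area
  at low pressure, i.e. looser packing;
- the **LE–LC transition**, a low-slope stretch where liquid-expanded and
  liquid-condensed phase coexist;
- the **collapse pressure**, the terminal pressure maximum where the film
  buckles into the third dimension;
- the **compressibility modulus**
  $C_s^{-1} = -A\,(\partial\pi/\partial A)$, whose maximum measures how
  rigidly the condensed film packs, conventionally compared at 30–35 mN/m,
  the lateral pressure attributed to biological membranes;
- the condensed-state **surface potential** and, through the Helmholtz
  parallel-plate model $\Delta\psi = \mu_\perp / (\varepsilon_0 A)$, the
  apparent dipole moment per molecule, reported in millidebye as
  $\mu_\perp[\mathrm{mD}] = A[\mathrm{Å^2}]\,\Delta\psi[\mathrm{mV}]/(12\pi)$.

`monolayr` implements this analysis as a tidyverse-style pipeline —
`read_isotherm()` / `generate_isotherm()` → `smooth_isotherm()` →
`compute_compressibility()` → detectors → `extract_features()` →
`build_feature_table()` / `compare_to_control()` — together with a synthetic
generator that produces isotherms with known landmarks, so the whole chain
can be validated against injected ground truth.

## The synthetic generator

The noiseless pressure backbone is piecewise in compression order, continuous
at every joint:

1. **Gas region**: $\pi = 0$ above the area $A_0$ where the LE branch
   reaches zero.
2. **Liquid-expanded branch**: the Volmer equation of state
   $\pi(A) = kT/(A-\omega) - \Pi_{coh}$, with co-area $\omega$ and the
   cohesion pressure $\Pi_{coh}$ fixed by continuity so the branch crosses
   the lift-off pressure (default 0.5 mN/m) exactly at the requested
   lift-off area. $kT$ is expressed as 408.9 mN·Å²/m at 23 °C and scales
   linearly with absolute temperature (`kT_monolayer()`).
3. An optional **coexistence plateau** of small constant slope between two
   requested pressures.
4. **Liquid-condensed branch** of constant elasticity,
   $\pi(A) = \pi_0 + K\,\ln(A_0/A)$, which makes $C_s^{-1} \equiv K$
   analytically — the generator-side oracle for the modulus pipeline.
5. **Collapse**: $\pi$ is clipped at the collapse pressure and then declines
   with a gentle post-collapse slope, so the collapse readout is an attained
   maximum, matching how collapse pressures are read off experimental
   traces.

The surface potential backbone is the sigmoid
$\Delta\psi(A) = \psi_{max}/(1+\exp((A-A_\psi)/w_\psi))$; a negative
$\psi_{max}$ models films whose condensed-state potential runs negative.
Measurement noise is i.i.d. Gaussian per sample on both signals — the
simplest model consistent with a fixed smoothing window; real traces also
carry slow drift and barrier-speed artefacts that the generator deliberately
omits (see *Limitations*).

Parameters that would make a segment unreachable (for example an LE branch
that cannot attain the LC onset pressure above the grid floor) raise a
classed `parameter-infeasibility` error rather than producing a silently
truncated curve.

### Design choices in the generator

- **Lift-off anchor = detection floor (0.5 mN/m).** The lift-off detector's
  floor is `baseline + max(0.5, 5·robust SD)`. Anchoring the backbone's
  lift-off at the same 0.5 mN/m level makes "the injected lift-off area" and
  "the detectable lift-off area" the same quantity; anchoring lower would
  build a systematic offset into every recovery comparison, as large as
  ~14 Å² for the most expanded films where the LE slope is only
  ~0.015 mN/m per Å².
- **Continuity at the gas/LE joint.** The LE branch is extended upward until
  it reaches zero pressure instead of jumping from 0 to the anchor at the
  lift-off area; a jump would be unphysical and would bias any
  smoothing-based detector.
- **Collapse as clip-plus-decline** (default post-collapse slope
  0.2 mN/m per Å²) rather than a sharp pressure drop: the decline gives the
  peak detector a prominence to work with while keeping the attained
  maximum equal to the requested collapse pressure.

### The presets

`preset_spec()` builds generator parameterizations for three lipids × six
subphases whose landmark values — lift-off area, collapse pressure, maximal
$C_s^{-1}$ (used as the LC elasticity $K$), condensed-state potential — come
from a published summary table (`preset_table()`). The remaining geometry is
a fixed recipe:

- grid from $1.35\times$ the lift-off area down to a per-lipid floor
  (DPPE 12, DPPG 28, cardiolipin 40 Å²), 1000 points; this leaves at least a
  third of the grid in the gas region for baseline estimation;
- co-area $\omega = \min(0.45\,A_{lift},\ A_{floor})$ (the Volmer branch
  requires $\omega \le A_{min}$);
- LC onset pressure $\pi_t$: the smaller of 12 mN/m and the pressure at
  which the LE modulus would reach 60% of $K$ (so the condensed branch, not
  the LE shoulder, carries the modulus maximum), lowered in 0.5 mN/m steps —
  but never below 5 mN/m — until the LC branch spans at least 110 grid
  points, so its modulus plateau survives the smoothing applied before
  differentiation. The 5 mN/m floor keeps the liquid-expanded branch intact
  across the lift-off detector's fit band (up to 8 detection margins,
  i.e. 4 mN/m).
- potential sigmoid: midpoint at $\max(A_{lift},\ \text{window top})$ with
  width one seventh of its distance to the window bottom, which puts the
  sigmoid within a few mV of $\psi_{max}$ across the per-lipid comparison
  window (DPPE 30–40, DPPG 40–80, cardiolipin 50–100 Å²);
- noise defaults 0.2 mN/m and 5 mV, typical of a film balance with
  ±0.1 mN/m resolution.

All presets are generated without a coexistence plateau. The published
curves with explicit plateau ranges have $K \approx 50$–60 mN/m; inserting a
plateau of detectable contrast into those geometries would push the collapse
area below the feasible grid. Plateau construction and detection are instead
exercised by a dedicated synthetic parameterization (plateau from 15 to
22 mN/m, $K = 200$) in the test suite.

## Preprocessing and differentiation

`adjacent_average()` is an unweighted centered moving mean whose window
shrinks symmetrically at the edges (output length = input length, no phase
lag). An even window — including the conventional 50 — is realized as the
next odd window, 51, since a symmetric centered window needs odd length; the
substitution is messaged. `smooth_isotherm()` applies it to $\pi$ and
$\Delta\psi$ as functions of sample index (the compression grid is uniform,
so index and area smoothing are equivalent), records the configuration in
the isotherm's provenance metadata, and flags repeated smoothing.

`compute_compressibility()` differentiates the smoothed trace by central
differences on the area grid (one-sided at the ends) and restricts the curve
to $\pi \ge$ the lift-off pressure: below it the derivative of a near-zero
signal only amplifies noise. Smoothing is applied to the *signals before*
differentiation; additionally, the extremum and interval readouts
(`modulus_summary()`, `detect_transition()`) apply a light adjacent average
(one fifth of the analysis window) to the modulus itself. The reason is
variance, not bias: a central difference of a boxcar-smoothed signal is a
difference of nearly disjoint point pairs, so its point-to-point noise is
high-frequency and survives the trace smoothing; without the second, light
pass the *maximum* of the modulus over a few hundred points would be biased
upward by two to three noise standard deviations.

## Detector design

**Lift-off** (`detect_liftoff()`): the baseline is the median over the
largest-area 10% of samples, with a MAD robust SD; the crossing level is
`baseline + max(0.5, 5·SD)` with a hysteresis band at half the margin, so a
noise dip after the crossing cannot drag the readout into the film. The raw
crossing is then refined by fitting the hyperbolic two-dimensional
equation-of-state form $\pi = b/(A-\omega) - c$ (the shape shared by the
Volmer and van der Waals-type 2D EOS for fluid films) to the early rise —
between 0.5 and 8 detection margins above baseline — with the co-area
profiled out, and solving the fit at the detection level. A local quadratic
fit, with its compressed arm capped one margin above the level so the much
steeper condensed branch cannot leak in, is the fallback. On expanded films
whose LE slope is ~0.015 mN/m per Å², ±3 Å² of lift-off accuracy corresponds
to ~0.05 mN/m of level accuracy; benchmarking against oracle-shape variants
shows the implemented estimator sits at the information limit of such
traces at realistic noise.

**Collapse** (`detect_collapse()`): the first local pressure maximum along
compression with prominence ≥ 0.5 mN/m (five times the ±0.1 mN/m instrument
resolution). Peak location and height are taken from a *lightly* smoothed
copy of the trace (window ≈ one fifth of the analysis window): heavy
smoothing biases an attained maximum low by roughly the pre-collapse slope
times the half-window, which for coarse grids would exceed 1 mN/m. If the
trace is monotone to the end, a two-segment piecewise-linear fit (exhaustive
least squares over breakpoints, coarse grid then single-step refinement, in
index space) over the final third looks for a collapse shoulder; it is
accepted only when the second segment's implied modulus falls below 25% of
the maximum modulus, and the collapse pressure is then the second segment's
fitted value at the kink, which is immune to corner rounding. Otherwise the
run is deemed to have ended before collapse and the feature is absent —
absence is a result, not an error.

**LE–LC transition** (`detect_transition()`): local maxima of the (lightly
smoothed) modulus with prominence ≥ 10 mN/m bracket candidate coexistence
stretches; between each consecutive pair the longest contiguous run with
modulus < 50 mN/m is taken, and the winning run (largest pressure extent,
at least 1 mN/m) gives the onset and end pressures. The 50 mN/m threshold
separates near-zero coexistence plateaus from liquid-expanded shoulders; the
prominence floor keeps derivative noise (SD of a few mN/m) from fabricating
flanking maxima. The search is restricted to the compression leg (up to the
attained pressure maximum), since the post-collapse tail revisits low
pressures with near-zero modulus.

**Modulus summary** (`modulus_summary()`): maximum over the pre-collapse
part of the curve, the modulus interpolated at the 30 mN/m reference
(configurable to 35), and a phase label from the standard elasticity bands —
below 12.5 gaseous/transition, 12.5–100 liquid-expanded, 100–250
liquid-condensed, above 250 solid. These numeric bands are the conventional
monolayer classification; the label is reported because studies phrase
their comparisons in these terms without printing band edges.

**Surface potential** (`max_surface_potential()`): the extremum of largest
magnitude, with sign, of the smoothed potential inside the per-lipid
condensed-state window; windows are configurable and default to the ranges
quoted for each lipid. The dipole conversion uses the Gaussian-unit constant
$1/(12\pi)$ exactly, the field's customary form of the Helmholtz relation in
Å²·mV·mD units.

## Validation strategy and what it shows

The test suite validates each stage against an *independent* oracle rather
than against the code path it exercises: a brute-force finite-difference
modulus on raw samples versus the constant-elasticity construction (within
0.5%) and the Volmer closed form $A\,kT/(A-\omega)^2$ (within 1%); the
Helmholtz unit point $\mu_\perp = 1$ mD at $A = 12\pi$ Å², $\Delta\psi = 1$
mV; hand-computed adjacent-average examples; and exact arithmetic identities
for the comparison statistics. Parameter recovery is tested end-to-end: each
preset is generated with noise (0.2 mN/m, 5 mV) across 50 seeds and
`extract_features()` must recover lift-off within ±3 Å², collapse within
±1 mN/m, maximal modulus within ±5% and potential within ±10 mV in at least
90% of seeds. The structural test analyses one low-noise realization of all
18 presets and checks the assembled feature table.

Passing these tests shows the pipeline is numerically faithful to its models
and robust at instrument-like noise; it does not show robustness to features
of real traces the generator omits — baseline drift, barrier-pause
artefacts beyond simple duplicate-area rows, autocorrelated noise, or
genuinely gradual (non-piecewise) phase transitions.

## Problem sizes and runtime

Default grids are 1000 points per isotherm (2000 where a test probes
smoothing bias), the sizes typical of film-balance exports; the recovery
study is 18 presets × 50 seeds. The full suite runs in about two minutes on
one core, the acceptance script in about one.

## Known limitations

- The LE–LC transition detector presumes modulus contrast; on films whose
  condensed-branch elasticity is itself near the 50 mN/m threshold the
  reported interval can be spurious or absent.
- Lift-off on very expanded films is information-limited: at noise
  0.2 mN/m and LE slopes near 0.015 mN/m per Å², the ±3 Å² recovery band
  corresponds to just under two standard deviations of the best attainable
  estimator, so a few percent of realizations fall outside it.
- The dipole-moment profile uses the single-capacitor Helmholtz model with
  no three-layer decomposition, and no double-layer correction for charged
  films on ionic subphases.
- Decompression (hysteresis) analysis, mixed-film excess thermodynamics and
  image-based phase identification are out of scope.
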