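---
title: "Models and methods for respirometry analysis with oxytrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for respirometry analysis with oxytrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxytrace)
```

oxytrace analyses chamber respirometry of small fish end to end: raw
oxygen time series in, per-fish physiology out. This vignette is the
package's account of the models it fits, the defaults it chooses and
why, what its simulator does and does not emulate, and the numerical
decisions a careful user should know about.

## Conventions

Temperature in °C, pressure in kPa, dissolved oxygen in mg O₂ L⁻¹,
oxygen partial pressure in kPa, volume in L, body mass in kg (grams
only in Fulton's K, which is conventionally g/cm³-scaled), metabolic
rate in mg O₂ kg⁻¹ h⁻¹, time in seconds within traces and hours inside
rate arithmetic. Salinity defaults to 0: this is a freshwater package;
the linear salinity term of the solubility model is accepted for
generality but untested beyond it.

## Oxygen unit conversion

Conversions between concentration, partial pressure and percent air
saturation hinge on the air-saturation concentration
`o2_saturation_conc()`, computed from the Benson–Krause freshwater
solubility equations (the formulation behind the standard USGS oxygen
solubility tables), with water-vapour pressure and barometric
correction, and the O₂ mole fraction in dry air fixed at 0.20946. The
conversion is the two-point anchor: zero oxygen maps to 0 kPa and full
saturation maps exactly to the PO₂ of water-saturated air,
0.20946 × (BP − vapour pressure), with linearity in between. Round
trips are exact to floating-point; tests pin the 20 °C table value
(9.09 mg L⁻¹ at 1 atm).

Published mg/L↔kPa pairings for treatment bands (e.g. 3–4 mg L⁻¹
alongside 7–9 kPa) are not exactly consistent with solubility at every
temperature; the package treats such pairings as loose cross-checks,
never as calibration targets.

## The simulator: ground truth for every estimator

`simulate_intermittent_trace()` and `simulate_closed_phase()` generate
the two record types the pipeline consumes, from a `fish_truth()` whose
parameters are exactly the quantities the pipeline later estimates.
The study conditions they default to: 300 mL chambers; 20-min sealed
determinations alternating with 2-min flushes for 24 h; a 2-min
exhaustive chase plus 40 s air exposure preceding the first (MMR)
determination; juvenile fish of about 1.5 g and 5.5 cm; bath oxygen at
the treatment midpoint (7 mg L⁻¹ normoxia, 3.5 mg L⁻¹ low-oxygen);
temperatures 20/24/28 °C; background respiration kept below 15 % of
the resting rate.

Modelling choices, each the simplest form consistent with the
protocol:

* **Effective volume.** The respirometer volume is chamber minus fish,
  with fish density 1 g mL⁻¹ (neutral buoyancy), so a 1.5 g fish in a
  300 mL chamber leaves 298.5 mL.
* **Post-chase recovery.** Metabolic rate decays exponentially from
  MMR to SMR with a truth-level half-life (default 2 h). Within each
  determination the rate is held at its start-of-cycle value, so the
  first cycle recovers MMR exactly and late cycles recover SMR exactly
  in noiseless runs — the identity on which the end-to-end recovery
  tests rest.
* **Closed phase.** While PO₂ ≥ P_crit the fish regulates at SMR
  (linear concentration decline); below P_crit it conforms with rate
  proportional to PO₂ through the origin (exponential decline,
  integrated exactly rather than stepped). The trace ends at the first
  sample at or below the loss-of-equilibrium threshold, which is
  recorded as the LOE event.
* **Noise.** I.i.d. Gaussian sensor noise on concentration, default
  sd 0.02 mg L⁻¹ at a 1 s sampling interval. Neither value is taken
  from any instrument specification; they are declared defaults of
  realistic magnitude for fibre-optic probes.
* **Background.** Blank-chamber depletion is a per-litre property of
  the chamber water: the fish chamber's decline rate is
  Ṁo₂·BW/V_eff + blank slope. Daily blank measurements (optionally
  drifting between rinses) are what the correction step consumes.
* **Determinism.** One scenario seed drives everything; per-fish seeds
  are derived from it, so cohorts are exactly reproducible.

What the simulator does **not** emulate — and hence what passing
recovery tests do not show about real data: temperature effects on
metabolic rate (temperature enters only through labels and
solubility), within-determination metabolic drift, mixing transients,
probe drift and autocorrelated sensor error, tank/chamber random
effects, spontaneous activity, and any nonlinearity of oxy-conformity.
Recovery results bound estimator error under the stated error model
only.

## From trace to Ṁo₂

`segment_cycles()` uses phase labels when the file carries them.
Otherwise flush onsets are detected as sustained oxygen rises
exceeding 3× the local noise sd (estimated robustly from first
differences); detection runs on a short running-mean smoothed series
and boundaries are then refined to the raw pre-rise minimum and
post-rise maximum. On noiseless simulated data, detection reproduces
the labelled segmentation exactly. Windows are half-open
`[start, end)` in seconds; cycles deviating more than 10 % from the
nominal determination length (e.g. a truncated final cycle) are
dropped.

`fit_cycle_slope()` trims the first 60 s of each determination (a
mixing transient allowance — standard practice, configurable) and fits
OLS of concentration on time. The endpoint concentrations of the rate
equation are evaluated from the fitted line at the window bounds, not
from raw samples: identical in the noiseless limit, more robust under
noise, and algebraically the same as slope × duration. r² is defined
as 0 for a zero-variance response.

`background_correct()` interpolates the daily blank slopes linearly in
time at each cycle midpoint, converts through the same V/t/BW scaling
and subtracts. Cycles whose background exceeds 15 % of the provisional
resting rate (the lowest-10 % mean of corrected non-chase cycles) are
flagged; exactly 15 % passes. `qc_filter()` flags (never deletes)
cycles below the 1 mg L⁻¹ protocol floor, with r² below 0.90
(configurable; no published threshold exists so the default is a
conventional strict one), with oxygen gain, or with negative corrected
rate. Flagged cycles are excluded from SMR/MMR but stay in the output
table.

## SMR, MMR, scope, condition

SMR is the mean of the lowest ⌈0.10·n⌉ corrected, QC-passing,
non-chase determinations (minimum one; ties at the cutoff resolved by
cycle order so exactly k order statistics enter). The chase (MMR)
cycle is excluded from the pool — including it could only bias SMR
upward. Whether early settling cycles should also be excluded is a
judgement call; an optional settling-window argument exists and
defaults to off, since with ~24 h of cycles the lowest decile is
almost always late anyway. MMR is the first post-chase determination,
reported with a warning flag if that cycle failed QC. AAS = MMR − SMR,
flagged if negative. Fulton's K = 100·W/L³ uses grams and centimetres
so that typically proportioned fish score near 1.

## P_crit and hypoxia tolerance

`closed_phase_mo2()` converts the closed phase into (PO₂, Ṁo₂) points
by consecutive fixed 2-min bins: per-bin OLS slope through the same
volume/mass scaling, paired with the fitted mid-bin concentration
expressed in kPa. Binning mirrors the determination-style slopes of
the intermittent phase and controls noise; 2 min balances point count
against per-point slope variance. An incomplete trailing fragment
(less than half a bin) is discarded: its slope variance is many times
the others' and a single wild terminal point can otherwise manufacture
a spurious breakpoint.

`fit_pcrit()` fits the continuous two-segment ("broken-stick") model:
for a candidate breakpoint ψ the design {1, x, (x−ψ)₊} forces the
conforming and regulating lines to intersect at ψ, and ψ is chosen to
minimise SSE. The search evaluates every observed PO₂ value inside the
central 5–95 % quantile band (edge breakpoints are unidentifiable),
then refines by golden-section search inside the bracketing intervals
of the best three candidates; exact SSE ties go to the smallest ψ. On
noiseless piecewise data the breakpoint is exact; against an
exhaustive 0.001 kPa grid search the combined scheme agrees to better
than 0.01 kPa on noisy data while evaluating ~50× fewer candidates.
Collinear input (nothing but one line to fit) yields a degenerate fit
that carries the single-line solution and no breakpoint. Fitting is
done in kPa; mass-specific rates are used throughout.

Both published definitions of P_crit are available: the intersection
point of the two lines (the default and reported estimator) and the
PO₂ at which the conforming line crosses SMR
(`pcrit_smr_crossing()`), flagged when SMR lies above the fitted
plateau or the conforming slope is not positive. When the plateau
equals SMR the two coincide.

`confint()` on a `pcrit_fit` gives a percentile bootstrap interval
over case-resampled refits (default B = 199, minimum 100); degenerate
refits are dropped and counted. Simulation at the package's default
noise puts empirical 95 % coverage in the low-to-mid 0.9s — adequate
for a breakpoint, whose bootstrap distribution is lumpy by nature.
`detect_loe()` reads the loss-of-equilibrium annotation and reports
the oxygen level in both unit systems plus time since closure.

## Permutational ANOVA

`perm_anova()` implements the two-factor permutational univariate
ANOVA: pseudo-F from the sequential (Type I) sums-of-squares
decomposition in the fixed order A, B, A×B — the published analysis
does not state its SS type, and sequential SS keeps unbalanced designs
well-defined — with significance from unrestricted permutation of the
raw observations (not residuals), the observed assignment counted, so
p ≥ 1/(n_perm+1). For balanced designs the pseudo-F equals the
classical two-way F exactly, which the tests verify against `anova(lm())`
as an independent oracle. The permutation distribution is computed by
projecting all permuted responses onto a precomputed orthonormal basis
of the design, so 999 permutations cost one matrix multiply. Default
999 permutations; a zero-variance response returns F = 0, p = 1; a
design with no residual df flags the interaction untestable.
`pairwise_posthoc()` runs permutation t-style pairwise tests within a
significant factor, Holm-adjusted, and refuses (without `force`) to
run when the omnibus term is not significant. Tank effects are out of
scope: the package operates on pooled per-fish endpoints.

## Problem sizes

The shipped tests and the acceptance script size their simulations to
what the estimators need rather than what a full study would collect:
single-fish end-to-end checks at the default 1 Hz protocol; cohorts of
8–30 fish for SMR/MMR recovery; 50 closed phases for P_crit recovery
error and 200 for bootstrap coverage (B = 199); 100 datasets for the
breakpoint-oracle comparison; 1000 null datasets × 999 permutations
for type-I calibration of the permutation ANOVA.

## Known limitations

* The oxy-conformity model is linear through the origin; Michaelis–
  Menten-style conformity and oxygen-supply-capacity (α-line) P_crit
  variants are out of scope, as are rolling-window Ṁo₂ estimators and
  EPOC quantification.
* Background correction assumes blank slopes vary slowly (linear
  interpolation between daily blanks).
* Label-free cycle detection expects flush upticks well above sensor
  noise; heavily fouled or slow-flush systems should supply phase
  labels.
* The bootstrap interval is percentile-based; no studentised or BCa
  refinement is attempted.
* Mixed-effects modelling (tank as a random factor) is deliberately
  not provided; the permutation ANOVA operates on pooled data.
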