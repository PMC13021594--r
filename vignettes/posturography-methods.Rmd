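---
title: "Methods: time-domain posturography with posturo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-domain posturography with posturo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(posturo)
```

This vignette is the package's own account of its methods: what is
computed, why each design choice was made where the method left room, and
what the synthetic cohort can and cannot stand in for.

## Signal model and conditioning

A recording is five synchronous 50 Hz channels over 30 s of quiet stance:
mediolateral (X) and anteroposterior (Y) CPF position in cm, moments about
the mediolateral and anteroposterior platform axes in N·m, and the
vertical force. Conditioning runs in a fixed order:

1. **Sliding median filter**, default kernel 5 samples (0.1 s). The kernel
   is a package choice: 5 samples removes 1–2-sample spike artifacts
   without smearing sway, and it is exposed as an argument for sensitivity
   work. Edges use reflection padding.
2. **Equiripple low-pass FIR**, passband edge 17 Hz, stopband edge 21 Hz,
   passband ripple at most 1 dB, stopband attenuation at least 80 dB.
   "Chebyshev-criterion FIR" is realised as a Parks–McClellan equiripple
   design (`signal::remez`), the canonical minimax construction. The order
   is searched upward from the Kaiser estimate until the response,
   measured by direct discrete-time Fourier summation on a 4096-point
   grid per band, meets both printed constraints; at 50 Hz this accepts
   order 54. The filter is applied in a single forward pass and the
   integer group delay of the symmetric design is removed by shifting;
   the printed attenuation figure describes a single pass, and a
   forward–backward pass would silently double it.
3. **Transient trim**: the first 15 s are discarded and exactly 600
   samples (12 s) retained. Subjects re-settle after stepping on the
   platform; recordings shorter than 27 s are rejected rather than padded,
   because padding would fabricate sway.
4. **Centering** of both positional channels (mean removal) and
   **z-scoring** of the weight channel. The normalized weight copy feeds
   the steady-phase threshold derivation only; moment computations use the
   filtered, un-normalized channels.

Filtering precedes trimming so that the trimmed window also discards the
filter's zero-padding edge response; artifact removal (median) precedes
spectral shaping so spikes cannot ring through the FIR. This order is a
package decision, fixed and covered by a regression test.

## The six features

* **C(Y)** — the central 95% amplitude range of the centered AP trace:
  97.5th minus 2.5th percentile, linear-interpolation percentiles
  (`quantile(..., type = 7)`). The "95% confidence amplitude" is read as
  an empirical coverage interval of the samples, not a parametric
  confidence interval — a coverage interval is what "encompassing 95% of
  the samples" describes, and it is distribution-free.
* **M(MY)** — `mean(|moment_y|) / mass`. The number is stored in the
  nominal units that result from N·m divided by kg, without dimensional
  reconciliation; it functions as a mass-normalized torque-activity index.
* **ZCR(Y), ZCR(X)** — strict sign changes of the centered position.
  Samples exactly at zero inherit the most recent nonzero sign, so a
  touch-and-return counts once, not twice; this avoids sampling-grid
  artifacts on nearly periodic traces. ZCR(X) is computed and retained for
  the correlation table although the six-feature set uses ZCR(Y) and
  ZCR(VX).
* **ZCR(VX)** — sign changes of the mediolateral velocity. Velocity is
  estimated by central differences (second-order accurate, phase-neutral),
  one-sided at the ends; a forward-difference variant is available behind
  an argument for sensitivity checks.
* **CRI(T)** — see below.
* **ST(N)** — count of samples whose summed 5-point moving variance of the
  two moment channels, divided by mass², is ≤ 0.002. The moving variance
  is the population variance (divisor 5) over the centered window, so the
  two samples at each end have no value and are never steady; ST(N) is a
  sample count (not an interval count), consistent with its observed
  magnitudes (tens to low hundreds within 600 samples). The 0.002 default
  is reproduced independently by `calibrate_threshold()`: the 25th
  linear-interpolation percentile — the upper limit of the lowest
  quartile — of per-subject mean moving variances of the normalized
  weight signal. The text behind this rule can be read as designating
  either the weight sample or the moment sample; under the implemented
  moment-variance rule both readings select the same index set, so the
  ambiguity is inert.

Romberg quotients are eyes-closed over eyes-open, the conventional
orientation in which values above 1 mean visual reliance. The RQ "path"
variant uses the full min–max (peak-to-peak) AP range, the literal reading
of "peak-to-peak sway path"; the central-95% variant is available from the
same feature table for sensitivity analysis.

## Stabilogram diffusion and the critical point

`compute_sdf()` evaluates the planar mean square displacement exactly over
all overlapping pairs for every sample lag up to 2.5 s. Planar (x² + y²)
displacement is the classical default for critical-point work; per-axis
curves are available by passing one axis. The 2.5 s cap reflects a 12 s
record: beyond roughly one fifth of the duration the empirical MSD is
variance-dominated.

`fit_critical_point()` scans every breakpoint with at least 4 lag points
on each side (the breakpoint belongs to both segments), fits each segment
by ordinary least squares, and minimizes pooled squared error; equal-SSE
ties go to the smaller breakpoint. CRI(T) is the intersection abscissa of
the two lines. The fit is **degenerate** when the slopes differ by less
than 5% of the steeper slope or the intersection leaves `(0, max lag)`;
degenerate values are excluded from cohort statistics, never imputed, and
the exclusion count is visible in the feature table (`cri_degenerate`).
On an exactly piecewise-linear curve the construction is exact; on a
noiseless mean-reverting curve `2*sigma^2*(1 - exp(-t/tau))` with
`tau = 1 s` the SSE-optimal two-line intersection sits slightly below the
relaxation time (the short line is a chord, not the tangent at zero),
which is why the parameter-recovery test asserts a ±0.2 s band rather
than exactness.

The estimator-property test for monotonicity in `tau` uses 60 s records
and a 5 s lag window: at 600 samples and 2.5 s of lag the estimator
saturates between `tau = 1.5` and `2 s`, which is a property of the 12 s
protocol, not of the estimator, and the test is about the estimator.

## The synthetic sway generator

There is no public recording set to test against, so the generator is a
first-class module whose defaults define the emulated study conditions:
50 Hz, 30 s per condition, eyes-open and eyes-closed, with per-sex,
per-age-group target feature means and group sizes in
`default_cohort_spec()` (male sizes 176/588/590/431/140 summing to 1,925;
female sizes 318/809/760/594/182 summing to 2,663 — the printed female
group sizes sum to one less than the printed female total, and the group
rows are used verbatim rather than resolving the discrepancy).

Per axis, position is a Gaussian-smoothed Ornstein–Uhlenbeck process:

* `sigma` (cm) — stationary sway scale; steers C(Y) almost linearly.
* `tau` (s) — mean-reversion relaxation time; places the diffusion-curve
  knee and hence CRI(T).
* `smooth` (s, Gaussian kernel SD; defaults 0.05–0.06 s) — short-term
  persistence. Smoothing is what makes the short-term regime persistent
  (a raw OU path at 50 Hz flips sign far too often for realistic
  zero-crossing rates at relaxation times near 1 s).
* `noise` (cm, defaults a few thousandths of a cm) — in-band
  sensor/tremor noise. The conditioning chain imposes a smoothness floor,
  so this noise is the monotone dial for the zero-crossing rates; it is
  kept far below `sigma` so it does not disturb C(Y).

Moments couple to a further-smoothed copy of the sway through an
inverted-pendulum gain (`moment_gain`, per kg per cm, gravity folded in),
plus corrective control noise injected only during **active** phases of a
two-state quiet/active Markov gate. The gate's stationary quiet fraction
sets ST(N); mean dwell times are sub-second (total switching rate 3/s),
matching the short steady intervals seen in sway-density practice and
keeping the per-record steady-count variance manageable. The weight
channel is body weight plus a slow respiratory oscillation (0.24 Hz,
~14 breaths/min) and white sensor noise, sized so that the cohort
quartile statistic behind the steady-phase threshold reproduces the 0.002
default. Eyes-open recordings divide the positional scales by
`visual_gain` (default 1.3), giving Romberg quotients above 1; only the
ratio matters, so no independent eyes-open model is attempted.

`calibrate_group()` adjusts one dedicated knob per target in the priority
order C(Y) → CRI(T) → M(MY) → ST(N) → ZCRs (amplitude and relaxation
knobs are nearly orthogonal to the rest; the zero-crossing knobs are the
most coupled and therefore go last), using damped multiplicative updates
against mean extracted features over fresh replicates (default 40 per
iteration, up to 20 iterations, 10% relative tolerance). Because the
steady-phase count is the noisiest feature, convergence is only accepted
after an independent confirmation batch agrees; non-convergence raises a
classed error carrying the best-so-far parameters and residuals, so
callers can proceed deliberately with an imperfect calibration.

What the generator does **not** emulate: full-body biomechanics, height
effects (not modelled anywhere in the package), comorbidity or
fear-of-falling structure, non-stationarity beyond the two-state gate,
and realistic within-subject day-to-day variability. Passing tests
demonstrate that the pipeline recovers what the generator encodes — they
say nothing about measurement artifacts real platforms produce.

## Cohort statistics

* **Stratification**: five bins 65–69, 70–74, 75–79, 80–84, 85+,
  inclusive boundaries; ages below 65 are an error, not a silent drop.
* **Balancing**: per stratum, a seeded random subset of females equal in
  count to the males. Selection is reproducible from the seed.
* **Folds**: each sex shuffled, pairs arranged alternately M,F,M,F…, and
  split into 10 mutually exclusive folds of `floor(n_pairs/10)` pairs.
  Leftover pairs are fixed in training across all folds — with 1,925
  pairs this yields test folds of exactly 192 per sex.
* **Sex classification**: one binary tree per fold (`rpart`, Gini,
  minimum leaf 20, cost-complexity pruning at the internal-CV error
  minimum — unstated hyperparameters resolved to the era's standard
  classification-tree practice, all configurable). Accuracy is aggregated
  from per-fold confusion counts exactly.
* **"Wilcoxon test"** between independent groups is the rank-sum
  (Mann–Whitney) form, since the groups are unpaired. Indicator tables
  apply no multiplicity correction by default, matching the reporting
  convention they mirror; `p_adjust` enables a corrected variant.
* **Age models**: per sex, a linear model (or regression tree) of age on
  C(Y), ZCR(Y), CRI(T), ST(N). The headline error is the SD of
  cross-validated residuals; the in-sample SD, R² and F are reported
  alongside because the choice between them is not fixed by convention.
* **Log transform**: natural log on strictly positive features before
  modelling; non-positive values are excluded with a counted warning.
* **Sex coding** for correlation/logistic work: female = 1, male = 0
  (documented; the sign of sex correlations depends on it).
* **RQ battery**: correlation of the two quotient variants, rank-sum sex
  tests, 10-fold logistic sex-prediction accuracy, one-way ANOVA across
  age groups, and a 5-class decision-tree age-group accuracy over the
  printed bins (the class count for the tree is an interpretation — the
  source procedure is described only as a "5-year division"). An
  alternative fold description ("groups of 100 participants") conflicts
  with the 10-fold account; the 10-fold scheme is implemented.

## Problem sizes and numerical choices in the test suite

The suite is sized for a single CPU: oracle-equivalence checks run on
200-sample inputs where O(n²) references are exact; stochastic recovery
properties use 80–100 replicates; the directional-fidelity check
calibrates all ten cohort groups at 32 replicates per iteration and 24
subjects per group; full-scale counting checks (balancing, folds) run on
the complete 4,588-subject metadata table, which is cheap because no
signals are simulated. Tolerances in tests mirror the statements they
check: exact (`1e-12`–`1e-9`) for algebraic identities, ±0.2 s for the
relaxation-time recovery, 10% relative for calibration round trips.

Degenerate inputs are handled explicitly throughout: zero-variance weight
is an error (a z-score would divide by zero), an all-zero signal has zero
crossings by definition, a motionless recording yields C(Y) = 0 with a
degenerate critical point and an edge-adjusted maximal ST(N) of 596, and
constant features in models trigger warnings rather than silent NaNs.
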