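---
title: "Methods: movement metrics, Brownian bridge home ranges and the regression stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement metrics, Brownian bridge home ranges and the regression stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `catrange`, the
assumptions behind them, the tunable parameters with their defaults, what
the synthetic-cohort generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## 1. The analysis chain

`catrange` analyses GPS trajectories of free-roaming companion cats in
three outcome families:

1. **Time away from home base** — the fraction of tracked time spent
   outside a 50 m disc around the home anchor, modelled by beta regression
   (logit link, constant precision $\phi$).
2. **Daily distance moved** — per-day sums of between-fix great-circle
   distances, modelled after a Box–Cox power transform by a linear mixed
   model with a per-animal random intercept and AR1 day-to-day error
   correlation; rainfall enters as a daily covariate.
3. **Home range** — the area of the 95% isopleth of a Brownian bridge
   kernel utilization distribution (UD), modelled on the log10 scale by
   ordinary least squares after excluding extreme outliers (> 90 ha).

Each model is reduced by manual backward elimination on type-II
likelihood-ratio tests, screened for confounding (a > 20% coefficient
change when another variable is added or removed), and followed by
Tukey-adjusted pairwise contrasts for significant multi-level factors.

## 2. Trajectory cleaning

Cleaning mirrors standard telemetry quality control:

* **Sorting and anchoring.** Fixes are time-sorted (UTC internally); the
  home anchor defaults to the first fix, matching protocols that set the
  first coordinate to the home address.
* **Duplicate removal.** A duplicate is a *repeated timestamp* at
  consecutive positions; the first record wins. Coordinate-identical fixes
  at different times are legitimate (a resting animal) and are kept.
  Timestamp identity is the condition that breaks downstream $\Delta t$
  computations, which is why it defines the rule.
* **Speed filtering.** Between-fix speeds above a per-animal threshold are
  treated as position blunders. The threshold is 10 m/s when the track has
  at least `min_band_count = 3` segments in the 5–10 m/s band (an animal
  genuinely recorded at such speeds) and 5 m/s otherwise. The *destination*
  fix of the first violating segment is deleted and the scan restarts: a
  single blunder creates two violating segments, and destination-deletion
  removes it in one pass. The filter is idempotent.

Geometry uses a spherical Earth (haversine, $R = 6{,}371$ km); the ~13 m
device error dwarfs ellipsoidal corrections. All planar work (UD rasters,
simulator paths) uses an azimuthal equidistant projection centred on the
home anchor: distances from home are exact and pairwise distances are
within 0.1% over a 10 km span, which the test suite asserts.

## 3. Movement metrics

**Interval attribution.** The state (HOME/AWAY, 50 m disc, boundary
inclusive) is known only at fix times. Each inter-fix interval is
attributed wholly to the shared state when both endpoints agree, and split
50/50 across a transition. The split is unbiased under symmetric crossing
times and exact in the dense-fix limit. Intervals are cut at local
midnight (default timezone `Europe/Copenhagen`) so per-day totals are
exact; per-day tracked seconds are reported alongside so low-coverage days
are visible rather than silently deflating outcomes. "Hours away per day"
is normalised by tracked time ($24 \cdot \sum \text{away}/\sum
\text{tracked}$).

**Distance.** Each between-fix segment is assigned to the calendar day of
its destination fix (splitting segments at midnight changes totals
negligibly and is not implemented). First and last tracking days are
trimmed before modelling, since animals are typically not tracked for
those whole days. Cats with an empty interior calendar day are flagged
`interrupted` and excluded from the distance model (day-level granularity:
a 23 h within-day gap does not trigger the flag).

**Boundary adjustment.** The pooled away fraction is mapped into $(0,1)$
by the Smithson–Verkuilen transform $(y(n-1)+0.5)/n$ with $n$ the cohort
size, because the beta likelihood is undefined at the boundaries.

## 4. Brownian bridge kernel home range

For a segment from $z_a$ (time 0) to $z_b$ (time $\Delta t$), the bridge
position at relative time $t \in (0,1)$ is bivariate normal with mean the
linear interpolation and variance

$$s^2(t) = \Delta t\, t(1-t)\,\sigma_1^2 + (1-t)^2\delta^2 + t^2\delta^2,$$

where $\sigma_1$ (m s$^{-1/2}$) is the diffusion coefficient and $\delta$
(m) the GPS location-error SD (default 13.1 m, the mean device error; a
per-fix override is supported). The UD is the time-weighted mixture of
these densities over all segments, discretised with $n_t = 10$ midpoint
nodes per segment on a raster with 10 m cells (about one device error);
doubling $n_t$ or halving the cell changes 95% areas by under 2% and 5%
respectively (asserted in tests). Segments spanning gaps longer than 4 h
are excluded and their time removed from the normalising constant —
bridges over tracking interruptions fabricate corridors. Isopleth areas
are computed by cell counting (smallest set of cells reaching the
cumulative level), which is exactly testable; polygonised contours are
deliberately not used.

**Estimating $\sigma_1$.** The classic leave-one-out construction scores
each odd-indexed interior fix under the bridge spanned by its two
neighbours. One deliberate correction to the textbook variance: the scored
observation carries its own location error, so the conditional variance of
the *observed* interior fix given the *observed* endpoints is

$$s^2_\mathrm{est}(t^\*) = T t^\*(1-t^\*)\sigma_1^2 +
\big[1 + (1-t^\*)^2 + t^{\*2}\big]\,\delta^2 .$$

Without the leading $\delta^2$ term the estimator absorbs the device noise
into $\sigma_1$ (empirically $\hat\sigma_1 \approx 1.1$ for a true 0.1 at
$\delta = 13.1$ — exactly the noise-compensating value), and no parameter
recovery is possible. With it, recovery on pure Brownian simulations is
accurate to a few percent whenever the diffusion signal is identifiable.
Identifiability is a real constraint: at $\delta = 13.1$ m and 5-minute
fixes, $\sigma_1 = 0.1$ contributes 1.5 m² of bridge variance against
~386 m² of noise (0.4% of the total), which no estimator can resolve from
500 fixes; the recovery sweep in the acceptance suite therefore uses a
precise device ($\delta = 2$ m). The 1-D likelihood search runs on
$[0, 5]$ m s$^{-1/2}$ with tolerance $10^{-6}$; hitting the upper bound
warns rather than fails.

A 100% minimum convex polygon utility is included for comparison with the
older literature only.

## 5. The regression stage

* **Beta regression** is fitted by direct maximum likelihood (BFGS on
  coefficients and $\log\phi$), standard errors from the inverse observed
  information, pseudo-$R^2$ as the squared correlation between the fitted
  linear predictor and the logit of the response. Tests pin the fit to an
  independent brute-force likelihood maximisation (coarse grid + polish).
* **Box–Cox** $\lambda$ maximises the standard profile likelihood (with
  Jacobian) over a grid $[-2, 2]$ in steps of 0.01. The *applied*
  transform is the simple power $y^\lambda$, not $(y^\lambda-1)/\lambda$:
  on the metres scale this keeps intercepts around $3500^{0.34} \approx
  16$, consistent with how such models are reported in the field; the
  normalised variant is available via `boxcox_mode = "normalized"`.
* **The distance mixed model** is fitted by profiled maximum likelihood:
  given the variance ratio $r = \tau^2/\sigma^2$ and $\rho$, the fixed
  effects are GLS and $\sigma^2$ is closed-form, leaving a 2-D bounded
  optimisation. AR1 correlation decays on *calendar-day offsets*
  ($\rho^{|\Delta \mathrm{day}|}$), so missing days weaken correlation
  instead of being treated as adjacent. The $r \ge 0$ bound is reachable
  exactly, so the degenerate fit ($\tau^2 = 0$, $\rho = 0$, via the `fix`
  argument) reproduces OLS to machine precision — the test suite's
  degenerate-limit oracle. nlme could fit the free model but cannot
  guarantee that boundary behaviour, which is why the likelihood is
  implemented directly.
* **Type-II tests** are likelihood-ratio comparisons of the model with and
  without each term, all other terms retained, on ML fits — chosen over
  Wald for uniformity across the three model kinds. On balanced orthogonal
  designs they coincide with sequential tests (asserted to $10^{-6}$).
* **Backward elimination** removes the largest-p term above the threshold
  (0.05 for the time-away and distance models, 0.10 for the home-range
  model) and refits until all remaining terms pass; the trace is returned.
* **Confounding** follows the operational > 20% rule: for each retained
  term, its coefficients are compared between models with and without each
  other variable; reference magnitudes below $10^{-8}$ are skipped with a
  note, since the relative change of a null coefficient is meaningless.
* **Post-hoc contrasts** use a reference grid (other factors at their
  reference level, numeric covariates at their mean), all pairwise
  differences with covariance-based standard errors and Tukey
  (studentized-range) adjustment. Two-level factors collapse to the
  coefficient's own test, with a note.
* **Rainfall predictions** evaluate the distance model at given rainfall
  amounts (factors at reference by default; sample-proportion averaging
  via `mode = "mean"`), build a 95% Wald interval on the transformed scale
  and back-transform through $y = (y^\*)^{1/\lambda}$.

The chi-squared **association screen** between categorical covariates runs
before modelling; within a flagged pair the variable flagged against more
partners (tie: later column) is proposed for exclusion — the study this
design follows removed two access-type variables this way, but the exact
tie-break was unstated, so the rule here is an explicit, configurable
convention. Expected cell counts below 1 switch the test to seeded Monte
Carlo p-values.

## 6. The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates a cohort with known ground truth. Defaults
describe the world the pipeline is validated against: 97 cats, 7 calendar
days (partial first and last day), covariate frequencies matching the
field cohort (4/45/3/45 sex-by-neuter split, thirds by age group, 81/16
nature access, ...), zero-inflated-gamma municipal rainfall, and a
wearable that fixes every 2–10 min while the animal moves, hourly while it
rests, with isotropic Gaussian error ($\delta = 13.1$ m).

**Movement model.** Days alternate exponential home dwells (mean 5 h,
stationary at a point jittered ~3 m from the anchor) with exponential
excursions (mean ~83 min): a straight transit to an attractor drawn around
the home (distance ~1.5$\sigma$), then a slow heading-persistent meander
(constant 0.17 m/s, 60 s legs, 20°/leg turning noise) that steers back
only beyond 1.8$\sigma$ from the attractor, and a straight return. The
paths are **piecewise linear**, so true path length and true time outside
the 50 m disc are computed *exactly* (segment–circle intersection), which
is the 1 s grid limit. A literally diffusive excursion process (OU sampled
every second) was rejected deliberately: diffusive paths have
scale-dependent length, so chord-sampled GPS distance can never come
within the stated 15% of a 1 s-grid truth — the recovery tolerance forces
a rectifiable world. Pure OU and pure Brownian track generators are
provided separately (`simulate_ou_track`, `simulate_bm_track`) for
validating the home-range estimator against closed forms
($A_{95} = \pi \sigma^2 \chi^2_{2,0.95}$).

**Device model.** The tracker is accelerometer-driven: when movement
resumes it wakes and fixes within 5–30 s, then samples on the moving
cadence. Without wake-on-motion, whole short excursions vanish inside
hourly gaps and distance recovery degrades by ~40%. Blunders (cell-tower
glitches) are emitted as burst fixes 20–45 s after a scheduled fix,
displaced 0.5–2 km — implying speeds above 11 m/s, which is what makes
them removable by the 5/10 m/s rule, as they were in the field protocol.

**Effect structure and calibration.** Older cats (> 7 y) roam less, nature
access increases roaming and range, intact males range widest, purebreds
move more than domestic shorthairs, and rainfall suppresses movement.
These enter as multipliers on excursion duration, meander speed and the
range scale $\sigma$. Defaults were calibrated **once** so that cohort
medians fall in the realistic bands (≈4 h/day away, ≈3 km/day, ≈5 ha 95%
range) and then frozen. The default rainfall slope (−0.02 per mm on the
log of excursion duration, with rainfall drawn with SD ≈ 7 mm) is steeper
than the ≈−0.009 implied by field prediction tables: at the field
magnitude the effect is undetectable against the simulator's bout-level
variance at $n = 97 \times 5$ days, and the end-to-end acceptance check
requires the pipeline to *retain* rainfall through elimination in ≥ 95%
of runs. The simulator emulates none of: habitat geometry, road avoidance,
cat–cat interactions, seasonality, autocorrelated GPS error. A green
pipeline therefore establishes *method correctness on a known world*, not
ecological realism.

**Known recovery limits.** With hourly resting fixes at $\delta = 13.1$ m,
every stationary hour contributes $\mathbb{E}\,\|\varepsilon_1 -
\varepsilon_2\| = \delta\sqrt{\pi}\cdot\sqrt{2}/\sqrt{2} \approx 23$ m of
spurious chord length (~0.45 km/day for a mostly-home cat). Distance
recovery is therefore asserted per cat only above ~1 km/day of true
movement, and always at the cohort aggregate; away-fraction recovery
(±0.05) holds per cat unconditionally.

## 7. Numerical choices and degenerate inputs

* UD mass normalisation asserted to $10^{-6}$ on every grid.
* `optimize`/`optim` tolerances: $10^{-6}$ for $\sigma_1$; `reltol`
  $10^{-12}$ for beta regression; L-BFGS-B with `factr` $10^{5}$ for the
  mixed model.
* Single-level factors (possible in small cohorts) are dropped from
  designs; aliased columns are pruned by pivoted QR; terms contributing no
  parameters are reported untestable rather than given fake p-values.
* The pipeline trims its candidate covariate list to the data's capacity
  (at least 3 residual d.f.), logging the decision, so pilot-sized cohorts
  run end to end.
* All randomness in the pipeline is seed-controlled; identical config +
  seed reproduce byte-identical report tables (asserted).

## 8. Known limitations

* The bridge estimator assumes a single $\sigma_1$ per animal; behaviour-
  switching (dynamic BBMM) variants are out of scope.
* Raster cell-counting slightly over-counts isopleth area at coarse cells
  (half-cell boundary bias); the convergence test bounds this below 5%.
* The AR1 fit profiles a single global $\rho$; per-animal correlation is
  not modelled.
* Marginal means use reference-level marginalisation by default; with
  unbalanced cohorts, population-averaged predictions (`mode = "mean"`)
  can differ noticeably.
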