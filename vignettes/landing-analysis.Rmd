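---
title: "Jump-landing analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jump-landing analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landkin)
```

`landkin` analyzes the landing phase of gecko jumps from digitized 2-D
marker trajectories and validates itself against a forward simulator with
exact ground truth. This vignette is the package's account of the science:
the models it implements, the conventions and tunable parameters it adopts,
the numerical decisions behind them, and what its validation does and does
not demonstrate.

## Coordinate conventions

All positions are in metres with x horizontal and y vertical **increasing
downward**, so gravity acts in +y and the animal travels in the −x
direction. Frames are 0-based; time is `frame × dt` with `dt = 1/fps`
(2000 fps by default, the recording rate the pipeline is designed around).
During landing analysis, time is re-anchored so that first contact is t = 0.

The landing platform is a plane of incline φ (degrees from horizontal)
through an anchor point. Its in-plane direction vector is `h(φ) =
(−cos φ, sin φ, 0)` — stored in the conventional unnormalized integer forms
`(−1,0,0)`, `(−1,1,0)`, `(0,1,0)` for the canonical 0°/45°/90° inclines —
and its unit normal is `e(φ) = (sin φ, cos φ, 0)`. The two are orthogonal
for every φ, and the incidence-angle formula normalizes `h` internally, so
the unnormalized 45° form has no numerical consequence (this is covered by
a test). Vectors carry a constant zero third component only inside the
impact-model operations, which are written as 3-vectors; storage is 2-D.

## Smoothing and differentiation

Digitization noise must be removed before differencing, and it is removed
exactly once: each marker's x(t) and y(t) are smoothed with a degree-5
(quintic) penalized B-spline with a third-derivative penalty
(`mgcv::smoothCon` supplies the basis and penalty), and every downstream
quantity — speed, acceleration, contact detection, the landing velocity
vector — is derived from the smoothed coordinates.

Two choices matter here:

- **One penalty for both coordinates.** The penalty is selected by
  generalized cross-validation on the *summed* residual sum of squares of x
  and y. Because both coordinates share one linear smoother, smoothing
  commutes with rotations and translations of the digitizing frame, a
  property the test suite checks to 10⁻⁹ m. Per-coordinate GCV would break
  it. The GCV search brackets log₁₀ λ in [−14, 6] with an optimizer
  tolerance of 10⁻⁹; coordinates are mean-centred before the linear solve
  to keep rounding error far below that budget. A fixed penalty can be
  supplied (`smoothing = list(method = "fixed", lambda = ...)`) for exact
  reproducibility.
- **The smoothing parameter is not prescribed by the source method**, which
  names only the spline family. GCV per track is the package's default and
  is flagged as a convention, not a reproduction.

The basis dimension defaults to `min(n − 2, max(20, n/3))` functions for an
n-frame track: fine enough to resolve a ~20 ms deceleration pulse at
2000 fps, while keeping each fit a few milliseconds. Very sharp pulses
(a ~2.5 ms pulse, as the horizontal-landing preset implies) sit at the
resolution limit and are attenuated; see *Known limitations*.

Speed is defined as the **norm** of the frame-to-frame displacement divided
by `dt`, aligned to the earlier frame (a forward difference), and
acceleration as the forward difference of that speed. These match the
field's frame-wise definitions literally; no centred-difference refinement
is applied, trading numerical elegance for fidelity. A consequence of the
norm: a marker that reverses direction shows a speed minimum, not a sign
change, and free fall shows a ≈ +g. Peak deceleration is −1 × the most
negative acceleration in the landing window; a window with no deceleration
returns a non-positive value flagged with a warning rather than an error.

## Landing metrics

- **First contact (t₀)**: the first frame at which any body marker (snout,
  belly, tail base — the eye is a head-orientation marker, not a contact
  surface, and is excluded) lies within ε of the platform plane. ε defaults
  to 2 mm, roughly the toe-pad scale. A manual annotation always overrides
  auto-detection, because limb contacts are invisible to a three-marker
  pipeline. The literal threshold rule carries a deterministic bias of
  about ±2–3 frames (≈1 ms) at typical approach speeds — e.g. a marker
  approaching at 1.6 m/s crosses a 2 mm threshold 2–3 frames before
  touching — which is small against every reported quantity.
- **Landing duration (T)**: the time from t₀ to the belly's closest
  approach, operationalized as the argmin of the belly-to-plane distance at
  or after t₀ (earliest frame on ties, via `which.min`). A belly still
  approaching at the last frame raises a "truncated landing" error. This
  operationalizes the verbal rule "when the body reached its closest
  position to the substrate".
- **Head angle (γ)**: the signed angle of the snout→ventral-eye line above
  horizontal, nose-up positive, computed as `atan2(Δy, |Δx|)` in the y-down
  frame. Evaluated at t₀ it is the landing angle; at the last take-off
  contact, the take-off angle; per-frame across the aerial window it gives
  the rotation series, whose net value telescopes exactly
  (γ_landing = γ_takeoff + net rotation). Negative-angle handling (the +3°
  offset before log-transforming) lives in the statistics module; raw
  angles are reported signed.
- **Body curvature (q/p)**: per frame, p is the snout to tail-base chord
  length and q the perpendicular deflection of the belly from that chord;
  the ratio is dimensionless and invariant under rigid transforms and
  uniform scaling (tested over 10³ random similarity transforms). Chords
  shorter than 10⁻⁴ m are skipped with a warning. The maximum over the
  landing window is reported.
- **Impact force**: `F_i = m (v/T) sin α + m g cos φ`, where v is the
  *speed* (norm) of the smoothed belly velocity vector taken between the
  frame before and the frame of first contact, and α comes from the arccos
  formula against `h`. `v/T` is an average-deceleration surrogate; the
  frame-wise peak deceleration is reported separately and never substituted
  into the force equation. The closed form equals the numeric projection of
  the full force vector onto the surface normal (checked against a
  brute-force oracle over 10⁵ random parameter draws to 10⁻¹⁰ N), gravity
  drops out exactly at φ = 90°, and F_i → m·g in the slow-drop limit on a
  horizontal surface.
- **Adhesion**: the published mass-scaling relation for single-forelimb
  frictional adhesion is printed as *Adhesion = 1.041(body mass) − 0.69*,
  which read linearly is dimensionally inconsistent with the ~10 N force it
  is known to predict at adult mass. The package adopts the log₁₀–log₁₀
  reading, `10^(1.041·log₁₀(mass_g) − 0.69)` N, which reproduces that
  figure; this interpretation is a documented decision. The safety factor
  is simply adhesion over impact force.

## The statistical decision tree

Trials are averaged per individual × treatment before any inference, making
the individual the experimental unit (pseudoreplication guard; missing
cells are an error, not silently dropped). Then, per metric, at α = 0.05:

1. Shapiro–Wilk per treatment group and Levene's test across groups
   (`car::leveneTest`).
2. Both pass → repeated-measures ANOVA: `nlme::lme` with a random intercept
   per individual. The rule "individuals were removed from the model when
   not significant" is operationalized as a REML likelihood-ratio test of
   the random intercept against `nlme::gls`; at p ≥ 0.05 the model is refit
   as a fixed-effects ANOVA. Pairwise contrasts use `multcomp::glht` with
   the single-step adjustment. Because that adjustment integrates a
   multivariate t numerically with Monte-Carlo error, the package pins the
   RNG locally (restoring the caller's state) so identical inputs always
   give identical reports.
3. A failed gate triggers a transform — an optional constant offset (+3°
   for the landing angle, to clear slightly negative values) followed by
   decadic logarithm — and the gates are re-checked. The transform is
   recorded in the report and is only ever entered after a failed gate.
4. If the transform is unavailable (non-positive values) or the gates still
   fail, the comparison falls back to Kruskal–Wallis, with Dunn's rank-based
   post-hoc z-tests (standard tie correction, unadjusted p-values unless
   configured — the source procedure states no adjustment) when the omnibus
   test is significant. Post-hoc results are never computed without a
   significant omnibus test.

The exact contrast and adjustment settings of the original analysis are
unstated; the defaults above are documented as the package's own. Group
summaries are reported as mean ± standard error. Under 500 null simulations
(4 individuals × 3 treatments of N(0,1) values) the tree's rejection rate
is checked to sit near the nominal 0.05.

## The simulator: what it emulates, and what it does not

`simulate_jump()` produces one trial with exact ground truth:

- **Flight** is pure projectile motion, integrated backward from the
  contact state so that the belly meets the plane with exactly the
  configured contact speed and incidence angle. Take-off state (speed,
  height drop) follows from the ballistics and is recorded as ground truth;
  contact speed therefore obeys energy bookkeeping exactly.
- **Landing** prescribes the belly's speed magnitude — a raised-cosine
  deceleration pulse whose peak equals the configured peak deceleration,
  decaying to a residual creep speed (default 0.1 m/s) — and a direction
  angle that rotates smoothly from the incidence angle to surface-parallel
  at exactly the configured landing duration, then past it, so the belly's
  closest approach lands on the configured T. The printed treatment means
  of speed, duration, peak deceleration and curvature are not jointly
  consistent with a rigid point-mass stop, so the profile realizes each
  ground-truth metric exactly rather than pretending to a single rigid-body
  dynamics.
- **Markers** sit on a rigid chord of snout–vent length through the belly,
  oriented so the designated contact marker (snout on the 45° and vertical
  platforms, tail base on the horizontal — matching the dominant observed
  first-contact parts) touches the plane exactly at t₀; during landing the
  chord is displaced along its own normal so the measured q/p follows a
  smooth bow peaking at the configured maximum curvature at the landing
  end. The eye is placed so the head angle ramps linearly over the aerial
  phase to the configured landing angle. Placement is *kinematic*: every
  ground-truth metric is realized exactly, at the cost of postural realism
  (a snout may recoil off the wall as the body bows; the chord may lift
  during a horizontal landing). Plots of simulated markers are therefore
  not anatomical reconstructions.
- **Noise** is i.i.d. Gaussian per coordinate and frame, default sd 0.5 mm,
  standing in for manual-digitization error; the true magnitude and camera
  calibration of the original recordings are not reported, so this default
  is a labelled convention.
- **Approach geometry.** Incidence angles are not reported per treatment;
  the presets fix them at 55° (horizontal), 45° (45° platform) and 85°
  (vertical — a near-perpendicular collision, as observed). The approach
  side of the plane and the sign of the in-plane travel direction are
  chosen per incline so that contact is physical: a descent onto the floor,
  a steep drop onto the 45° face, and −x travel onto the wall.
- **Studies.** `simulate_study()` draws per-individual masses uniformly
  from 35.9–49.2 g and chord lengths from 11.37–12.74 cm (the study
  animals' ranges), jitters the positive ground truths log-normally
  (default CV 10%, mean-preserving) and the angles normally (sd 3° for the
  landing angle, 2° otherwise), and defaults to 4 individuals × 3
  treatments × 3 trials. All randomness flows from one integer seed; a
  fixed seed reproduces trajectory files bit for bit.

What passing the simulator-recovery tests shows: the pipeline's event
detection, smoothing, differentiation and vector algebra invert the
generative model to within noise and frame discretization (noise-free
recovery is tested at 2%; twelve noisy trials per treatment recover the
preset group means within 10–15%). What it does not show: robustness to
structured digitization artefacts (marker swaps, occlusion gaps,
calibration drift), to non-rigid bodies whose markers move relative to the
skin, to tail dynamics (tails keep moving after contact and are not
modelled), or to compliant landing surfaces. Real-data behaviour beyond the
modelled effects is untested by construction.

## Numerical choices and degenerate inputs

- Ties in the landing-end argmin resolve to the earliest frame.
- A degenerate (constant-position) track is returned unchanged by the
  smoother; tracks shorter than 8 frames are an error (a quintic basis
  needs support).
- First contact at frame 0 leaves no preceding frame for the velocity
  vector and is an error; a trial whose markers never come within ε of the
  plane is a "no contact" error.
- The landing window must span at least two acceleration samples for a peak
  deceleration; otherwise the summary field is NA.
- Trajectory files are comma-delimited long form with `#` metadata
  comments; coordinates are written with 15 significant digits so
  write→read round-trips are the identity to well below 10⁻⁹ m. Units
  declared in the header (m/cm/mm, plus an optional px→m calibration
  factor) are converted at read time.
- Problem sizes throughout the test suite and the acceptance script — 12
  replicate trials per treatment for recovery checks, 500 null simulations
  for the type-I check, 10⁵ draws for the projection oracle — were chosen
  as the smallest sizes at which the Monte-Carlo error is comfortably
  inside the tolerance being checked.

## Interfaces

The package is a library: the exported functions (`analyze_trial()`,
`analyze_study()`, `simulate_study()`, plus the readers and writers) and
this vignette are its interface, and `scripts/acceptance.R` is a worked
end-to-end driver. Configuration can be supplied programmatically
(`analysis_config()`) or from a YAML/JSON file
(`read_analysis_config()`).

## Known limitations

- Peak deceleration on very short landings (~18 ms with a ~2.5 ms pulse) is
  attenuated by smoothing at 2000 fps; the vertical-platform pulse
  (~20 ms) is recovered well, and the impact-force model deliberately uses
  v/T rather than the frame-wise peak, so the headline force numbers are
  unaffected.
- Forelimb/hindlimb first contacts cannot be detected from a three-marker
  set; automatic detection reports the marker name (tail base serving as a
  hindlimb proxy), and annotations are required to reproduce limb-contact
  classifications.
- The generic trajectory reader makes no promise about third-party
  spreadsheet layouts; data must be in (or converted to) the documented
  long form.
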