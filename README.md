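# landkin

Landing biomechanics for jumping, pad-bearing geckos. Arboreal geckos cross
gaps by leaping and must arrest their momentum on whatever surface they hit —
a horizontal branch, an inclined trunk, a vertical wall. The incline of the
landing surface changes how much of the collision the adhesive toe pads must
absorb. `landkin` turns digitized high-speed-video marker trajectories
(snout, ventral eye, belly, tail base at 2000 fps) into the quantities that
describe a landing, and tests how they differ across landing-surface
inclines.

## What it computes

For each trial, from 2-D marker coordinates (x horizontal, y vertical
positive downward, metres):

- **Smoothed kinematics.** Each coordinate series is smoothed once with a
  quintic penalized B-spline (third-derivative penalty, shared-penalty
  bivariate GCV so smoothing is rotation-equivariant). Speed is the
  frame-wise displacement norm `v = s/Δt`; acceleration is the forward
  difference `a = (v₂ − v₁)/Δt`; peak deceleration is −1 × the most negative
  acceleration during landing.
- **Landing events.** First contact t₀ (first frame any body marker is
  within ε = 2 mm of the platform plane; manual annotations take
  precedence), and landing duration T (time from t₀ to the belly's closest
  approach to the plane).
- **Posture.** Head angle γ (signed angle of the snout→ventral-eye line
  above horizontal, nose-up positive) at first contact and take-off, net
  aerial rotation, and body curvature q/p — the perpendicular deflection of
  the belly from the snout–tail-base chord over the chord length.
- **Impact force.** The landing velocity vector `v⃗ = (Δx, Δy)/Δt` from the
  smoothed belly coordinates at first contact, its incidence angle
  `α = arccos(v⃗·h⃗ / |v⃗||h⃗|)` against the platform's in-plane direction
  `h⃗`, and the surface-normal impact force

      F_i = m (v/T) sin α + m g cos φ

  (inertial term plus gravitational projection, with φ the platform
  incline), together with `v⊥ = v sin α` and the adhesive safety factor
  against the forelimb adhesion predicted by the mass-scaling relation
  `10^(1.041·log₁₀(mass_g) − 0.69)` N.
- **Incline comparison.** Per-individual trial averaging (the individual is
  the experimental unit), Shapiro–Wilk and Levene gates at 0.05, then
  repeated-measures ANOVA (random intercept per individual, dropped when its
  likelihood-ratio test is non-significant) or — after an optional offset and
  log₁₀ transform fails to rescue the assumptions — Kruskal–Wallis with
  Dunn's post-hoc tests. Mass regressions via ordinary least squares.

A forward simulator (`simulate_jump()`, `simulate_study()`) generates
ballistic jump-and-land trials with Gaussian digitization noise and exact
ground truth for every metric, using the published treatment means as
presets; it is how the pipeline is validated end to end.

## Worked example

Simulate one vertical-platform trial and analyze it:

```r
library(landkin)
sim <- simulate_jump(simulation_config("vertical", seed = 42))
summary <- analyze_trial(sim$trial, sim$geom)
```

Output (one row of the trial summary, transposed):

```
landing_duration_s      0.071
landing_angle_deg      34.499
max_curvature           0.508
peak_deceleration_ms2 106.502
landing_speed_ms        1.681
incidence_angle_deg    85.752
v_perp_ms               1.677
impact_force_n          1.005
first contact: snout at frame 277
```

The gecko hits the vertical wall snout-first in a near-perpendicular
collision (α ≈ 86°) at 1.68 m/s, bows its body to a curvature of 0.51 while
taking 71 ms to settle, and experiences an impact force of about 1 N —
gravity contributes nothing on a vertical surface, so the whole force is the
inertial term. Against it:

```r
adh <- predicted_adhesion(summary$mass_kg * 1000)
safety_factor(adh, summary$impact_force_n)
#> forelimb adhesion 10.1 N, safety factor 10.1
```

`simulate_study()` generates a full 4-individual × 3-incline × 3-trial
study, and `analyze_study()` returns the per-trial summary table plus one
`test_report` per metric (chosen test, transform, omnibus and post-hoc
p-values).

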