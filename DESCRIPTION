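Package: landkin
Title: Jump-Landing Kinematics and Impact Forces on Inclined Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-speed-video landing kinematics of
    jumping geckos. Reads digitized 2-D marker trajectories, smooths them with
    quintic penalized splines, computes frame-wise speed and acceleration,
    detects first surface contact and landing duration, measures head angle and
    body curvature, and evaluates the surface-incline-projected impact force
    together with adhesive safety factors. Includes the repeated-measures
    statistical decision tree used to compare landing-surface inclines
    (assumption gating, RM-ANOVA or Kruskal-Wallis with Dunn post-hoc tests)
    and a ballistic jump simulator that generates marker data with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    car,
    multcomp,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
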