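# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except in explicit round-trip tests.

DT2000 <- 1 / 2000

# track whose position moves with constant velocity (m/s)
linear_track <- function(marker = "belly", n = 200, v = c(-1, 0),
                         origin = c(0.5, -0.3), dt = DT2000) {
  t <- (0:(n - 1)) * dt
  marker_track(marker, cbind(origin[1] + v[1] * t, origin[2] + v[2] * t), dt)
}

# minimal 3-marker trial built from one belly path; snout/tail ride rigidly
# above the belly so they never interfere with belly-based detection
rigid_trial <- function(belly_xy, dt = DT2000, mass = 0.042, treatment = 0,
                        offset = c(0, -0.05), ...) {
  n <- nrow(belly_xy)
  shift <- function(d) cbind(belly_xy[, 1] + d[1], belly_xy[, 2] + d[2])
  trial_recording(
    list(snout = marker_track("snout", shift(offset + c(-0.05, 0)), dt),
         belly = marker_track("belly", belly_xy, dt),
         tail_base = marker_track("tail_base", shift(offset + c(0.05, 0)), dt)),
    individual_id = "fix", mass = mass, treatment = treatment, fps = 1 / dt, ...)
}

# trial with an explicit eye marker at a prescribed head angle (degrees)
head_trial <- function(angle_deg, n = 10, dt = DT2000, eye_off = 0.013) {
  a <- angle_deg * pi / 180
  snout <- matrix(rep(c(0.1, -0.2), each = n), ncol = 2)
  eye <- cbind(snout[, 1] + eye_off * cos(a), snout[, 2] + eye_off * sin(a))
  trial_recording(
    list(snout = marker_track("snout", snout, dt),
         eye = marker_track("eye", eye, dt),
         belly = marker_track("belly", snout + 0.05, dt),
         tail_base = marker_track("tail_base", snout + 0.1, dt)),
    individual_id = "fix", mass = 0.042, treatment = 0, fps = 1 / dt)
}

# rotation that increases the measured head angle by theta when applied to
# marker positions (y axis points down throughout the package)
rot2 <- function(theta_deg) {
  r <- theta_deg * pi / 180
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
}

# balanced trial table for the stats pipeline: value = base effect per
# treatment + individual offset + per-trial residuals
metric_table <- function(means = c(0, 0, 0), n_ind = 4, n_trial = 3,
                         ind_sd = 0.5, resid = NULL, seed = 1) {
  set.seed(seed)
  trts <- c(0, 45, 90)
  rows <- expand.grid(trial = seq_len(n_trial), individual_id = sprintf("g%d", seq_len(n_ind)),
                      treatment = trts, stringsAsFactors = FALSE)
  ind_eff <- stats::rnorm(n_ind, 0, ind_sd)
  names(ind_eff) <- sprintf("g%d", seq_len(n_ind))
  eps <- if (is.null(resid)) stats::rnorm(nrow(rows), 0, 1) else resid(nrow(rows))
  rows$value <- means[match(rows$treatment, trts)] + ind_eff[rows$individual_id] + eps
  rows[c("individual_id", "treatment", "value")]
}
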