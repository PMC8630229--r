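test_that("first contact is the first frame a marker reaches the plane", {
  # belly descends (y-down) and touches y = 0 exactly at frame 57
  n <- 80
  y <- ((0:(n - 1)) - 57) * 1e-3  # 1 mm per frame, zero at 0-based frame 57
  belly <- cbind(rep(0.1, n), y)
  tr <- rigid_trial(belly)
  geom <- platform_geometry(0, anchor = c(0, 0))
  det <- detect_first_contact(tr, geom, epsilon = 1e-9)
  expect_identical(det$frame, 57L)
  expect_identical(det$part, "belly")

  # annotation always wins over auto-detection
  tr2 <- rigid_trial(belly, first_contact_frame = 60, first_contact_part = "forelimb")
  det2 <- detect_first_contact(tr2, geom, epsilon = 1e-9)
  expect_identical(det2$frame, 60L)
  expect_identical(det2$part, "forelimb")

  # never approaching the plane
  far <- rigid_trial(cbind(rep(0.1, 20), rep(-0.5, 20)))
  expect_error(detect_first_contact(far, geom, epsilon = 0.002), "no marker")
})

test_that("simulated contact frame is detected within 2 frames at 2 mm threshold", {
  for (s in c(101, 202)) {
    sim <- simulate_jump(simulation_config("vertical", seed = s))
    smoothed <- smooth_trial(sim$trial)
    det <- detect_first_contact(smoothed, sim$geom, epsilon = 0.002)
    expect_lte(abs(det$frame - sim$truth$t0_frame), 2)
    expect_identical(det$part, sim$truth$contact_marker)
  }
})

test_that("landing duration is the time to the belly's closest approach", {
  dmm <- c(10, 6, 3, 1, 0.5, 0.8, 1.1, 1.4, 1.9, 2.5)
  belly <- cbind(rep(0.1, 10), -dmm * 1e-3)
  tr <- rigid_trial(belly)
  geom <- platform_geometry(0)
  out <- landing_duration(tr, geom, t0 = 0)
  expect_equal(out$T, 4 * DT2000)
  expect_identical(out$end_frame, 4L)

  # plateau: two equal minima -> earliest wins
  dmm2 <- c(10, 6, 3, 0.5, 0.5, 0.8, 1.1, 2, 3, 4)
  tr2 <- rigid_trial(cbind(rep(0.1, 10), -dmm2 * 1e-3))
  expect_identical(landing_duration(tr2, geom, 0)$end_frame, 3L)

  # still approaching at the last frame -> truncated
  tr3 <- rigid_trial(cbind(rep(0.1, 10), -c(10, 8, 6, 5, 4, 3, 2.5, 2, 1.5, 1) * 1e-3))
  expect_error(landing_duration(tr3, geom, 0), "truncated")
})

test_that("head angle follows the snout-eye line with nose-up positive", {
  expect_equal(head_angle(head_trial(0), 0), 0)
  expect_equal(head_angle(head_trial(45), 0), 45, tolerance = 1e-12)
  expect_equal(head_angle(head_trial(-30), 0), -30, tolerance = 1e-12)

  # rotating the whole configuration by +10 degrees adds exactly 10 degrees
  tr <- head_trial(12)
  R <- rot2(10)
  rot_tracks <- lapply(tr$tracks, function(t) {
    marker_track(t$marker_name, t$positions %*% t(R), t$dt)
  })
  tr_rot <- trial_recording(rot_tracks, "fix", 0.042, 0, 2000)
  expect_equal(head_angle(tr_rot, 0), 22, tolerance = 1e-9)

  # missing eye marker: NA with a warning, not an error
  noeye <- rigid_trial(cbind(rep(0.1, 10), rep(-0.1, 10)))
  expect_warning(a <- head_angle(noeye, 0), "eye")
  expect_true(is.na(a))
})

test_that("aerial rotation telescopes and recovers a prescribed pitch ramp", {
  # constant attitude -> zero net rotation
  tr <- head_trial(20, n = 30)
  rot <- aerial_rotation(tr, c(0, 29))
  expect_equal(rot$net, 0, tolerance = 1e-12)

  # simulator with a 15 degree nose-up ramp
  sim <- simulate_jump(simulation_config("vertical", net_rotation = 15, noise_sd = 0))
  sm <- smooth_trial(sim$trial)
  rot <- aerial_rotation(sm, c(0, sim$truth$t0_frame))
  expect_equal(rot$net, 15, tolerance = 1)

  # landing angle = take-off angle + net rotation, exactly
  expect_equal(rot$angles[length(rot$angles)], rot$angles[1] + rot$net,
               tolerance = 1e-12)
})

test_that("body curvature matches hand geometry and degenerates to zero", {
  mk <- function(s, b, t) trial_recording(
    list(snout = marker_track("snout", matrix(s, 5, 2, byrow = TRUE), DT2000),
         belly = marker_track("belly", matrix(b, 5, 2, byrow = TRUE), DT2000),
         tail_base = marker_track("tail_base", matrix(t, 5, 2, byrow = TRUE), DT2000)),
    "fix", 0.042, 0, 2000)
  cs <- body_curvature(mk(c(0, 0), c(0.01, 0.01), c(0.02, 0)))
  expect_equal(cs$q[1], 0.01, tolerance = 1e-12)
  expect_equal(cs$p[1], 0.02, tolerance = 1e-12)
  expect_equal(cs$max_curvature, 0.5, tolerance = 1e-12)

  collinear <- body_curvature(mk(c(0, 0), c(0.01, 0), c(0.02, 0)))
  expect_equal(collinear$max_curvature, 0, tolerance = 1e-12)

  # one degenerate frame is skipped; the rest still yield a maximum
  tailpos <- matrix(c(0.02, 0), 5, 2, byrow = TRUE)
  tailpos[3, ] <- c(0, 1e-5)
  degen <- trial_recording(
    list(snout = marker_track("snout", matrix(c(0, 0), 5, 2, byrow = TRUE), DT2000),
         belly = marker_track("belly", matrix(c(0.01, 0.01), 5, 2, byrow = TRUE), DT2000),
         tail_base = marker_track("tail_base", tailpos, DT2000)),
    "fix", 0.042, 0, 2000)
  expect_warning(cd <- body_curvature(degen), "degenerate")
  expect_equal(cd$max_curvature, 0.5, tolerance = 1e-12)
})

test_that("curvature is invariant under rigid transforms and scaling", {
  set.seed(5)
  base <- list(s = c(0, 0), b = c(0.013, 0.009), t = c(0.021, -0.004))
  ref <- with(base, abs((t[1] - s[1]) * (b[2] - s[2]) - (t[2] - s[2]) * (b[1] - s[1])) /
                sum((t - s)^2))
  for (i in 1:25) {
    R <- rot2(runif(1, -180, 180))
    sc <- exp(runif(1, -2, 2))
    sh <- runif(2, -1, 1)
    pts <- lapply(base, function(p) as.numeric(sc * R %*% p + sh))
    tr <- trial_recording(
      list(snout = marker_track("snout", matrix(pts$s, 4, 2, byrow = TRUE), DT2000),
           belly = marker_track("belly", matrix(pts$b, 4, 2, byrow = TRUE), DT2000),
           tail_base = marker_track("tail_base", matrix(pts$t, 4, 2, byrow = TRUE), DT2000)),
      "fix", 0.042, 0, 2000)
    expect_equal(body_curvature(tr)$max_curvature, ref, tolerance = 1e-9)
  }
})

test_that("take-off detection is monotone in epsilon and speed is read at the frame", {
  # tail_base sits on the take-off plane then lifts off quadratically
  n <- 60
  t <- (0:(n - 1)) * DT2000
  lift <- pmax(0, t - 0.01)^2 * 200
  belly <- cbind(0.4 - 1.5 * t, -0.05 - lift)
  tr <- rigid_trial(belly, offset = c(0, 0.05))  # tail at belly + (0.05, 0.05)... see below
  # place the tail explicitly on the plane y = -0.02 - lift
  tracks <- tr$tracks
  tracks$tail_base <- marker_track("tail_base", cbind(0.45 - 1.5 * t, -0.02 - lift), DT2000)
  tr <- trial_recording(tracks, "fix", 0.042, 0, 2000)
  geom_to <- platform_geometry(0, anchor = c(0, -0.02))
  frames <- vapply(c(1e-6, 1e-4, 5e-4, 2e-3, 5e-3), function(eps) {
    detect_last_takeoff_contact(tr, geom_to, eps)
  }, 1L)
  expect_true(all(diff(frames) >= 0))

  # stationary trial -> zero take-off speed
  still <- rigid_trial(matrix(0.1, 20, 2))
  expect_equal(takeoff_velocity(still, 0), 0)
  expect_error(takeoff_velocity(still, 50), "outside")
})

test_that("noise-free simulated trials are recovered within discretization error", {
  sim <- simulate_jump(simulation_config("vertical", noise_sd = 0))
  res <- analyze_trial(sim$trial, sim$geom)
  tru <- sim$truth
  expect_equal(res$takeoff_speed_ms, tru$takeoff_speed, tolerance = 0.02)
  expect_equal(res$landing_duration_s, tru$landing_duration, tolerance = 0.02)
  expect_equal(res$incidence_angle_deg, tru$incidence_angle, tolerance = 0.02)
  expect_equal(res$max_curvature, tru$max_curvature, tolerance = 0.02)
  expect_equal(res$landing_angle_deg, tru$landing_angle, tolerance = 0.02)
  # landing window contains the frame of peak deceleration
  ser <- compute_acceleration(compute_velocity(smooth_track(sim$trial$tracks$belly)))
  pk <- ser$a_frame[which.min(ser$a)]
  expect_gte(pk, res$t0_frame)
  expect_lte(pk, res$landing_end_frame)
})
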