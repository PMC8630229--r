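test_that("landing velocity vector reads the smoothed belly displacement", {
  tr <- linear_track(v = c(-1.5, 0), n = 60)
  v <- landing_velocity_vector(tr, 30)
  expect_equal(unname(v), c(-1.5, 0), tolerance = 1e-9)
  expect_error(landing_velocity_vector(tr, 0), "frame 0")

  # norm equals the kinematics speed for the interval ending at t0
  set.seed(3)
  t <- (0:199) * DT2000
  pos <- cbind(0.4 - 1.3 * t + 3 * t^2, -0.3 + 0.7 * t) +
    matrix(rnorm(400, 0, 3e-4), ncol = 2)
  sm <- smooth_track(marker_track("belly", pos, DT2000))
  ser <- compute_velocity(sm)
  t0 <- 120
  expect_equal(sqrt(sum(landing_velocity_vector(sm, t0)^2)),
               ser$v[t0], tolerance = 1e-9)
})

test_that("free-fall landing velocity matches analytic ballistics", {
  t <- (0:449) * DT2000
  pos <- cbind(0.3 + 0 * t, -0.4 + 0.5 * 9.81 * t^2)
  sm <- smooth_track(marker_track("belly", pos, DT2000))
  v <- landing_velocity_vector(sm, 400)  # t0 = 0.2 s of fall
  expect_equal(v[["y"]], 9.81 * 0.2, tolerance = 0.02 * 9.81 * 0.2)
})

test_that("incidence angle reproduces hand-computed cases", {
  expect_equal(incidence_angle(c(-1, 0), platform_geometry(0)), 0, tolerance = 1e-12)
  expect_equal(incidence_angle(c(-1, 1), platform_geometry(0)), 45, tolerance = 1e-12)
  expect_equal(incidence_angle(c(-1, 0), platform_geometry(90)), 90, tolerance = 1e-12)
  # unnormalized 45-degree direction vector is normalized internally
  # (arccos loses precision near 0, hence the looser tolerance)
  expect_equal(incidence_angle(c(-1, 1), platform_geometry(45)), 0, tolerance = 1e-5)
  expect_error(incidence_angle(c(0, 0), platform_geometry(0)), "zero")
})

test_that("impact force matches the closed form and its decomposition", {
  r <- impact_force(m = 0.04255, v = 1.66, T = 0.0697, alpha = 90, phi = 90)
  expect_equal(r$F_i, 0.04255 * (1.66 / 0.0697), tolerance = 1e-12)
  expect_equal(r$v_perp, 1.66, tolerance = 1e-12)
  expect_equal(r$F_i, r$inertial_term + r$gravitational_term, tolerance = 1e-15)
  expect_equal(r$omega, 0)
  expect_error(impact_force(0.04, 1.5, 0, 45, 0), "positive")
})

test_that("closed form equals the numeric projection of the force vector", {
  set.seed(9)
  n <- 2000
  m <- runif(n, 0.01, 0.1); v <- runif(n, 0.1, 3); T <- runif(n, 0.005, 0.15)
  alpha <- runif(n, 0, 180); phi <- runif(n, 0, 90)
  err <- vapply(seq_len(n), function(i) {
    om <- (alpha[i] - phi[i]) * pi / 180
    pr <- phi[i] * pi / 180
    Fvec <- c(m[i] * (v[i] / T[i]) * cos(om),
              m[i] * (v[i] / T[i]) * sin(om) + m[i] * 9.81)
    e <- c(sin(pr), cos(pr))
    abs(sum(Fvec * e) - impact_force(m[i], v[i], T[i], alpha[i], phi[i])$F_i)
  }, 1)
  expect_lt(max(err), 1e-10)
})

test_that("the expanded trigonometric form collapses to the compact one", {
  grid <- expand.grid(alpha = seq(0, 180, by = 15), phi = seq(0, 90, by = 15))
  m <- 0.042; v <- 1.7; T <- 0.03; g <- 9.81
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i] * pi / 180; p <- grid$phi[i] * pi / 180
    expanded <- m * (v / T) * (cos(a) * cos(p) * sin(p) + sin(p) * sin(a) * sin(p) +
                                 sin(a) * cos(p) * cos(p) - sin(p) * cos(a) * cos(p)) +
      m * g * cos(p)
    expect_equal(impact_force(m, v, T, grid$alpha[i], grid$phi[i], g)$F_i,
                 expanded, tolerance = 1e-12)
  }
})

test_that("limiting cases and monotonicity properties hold", {
  m <- 0.04255
  # vertical surface: gravity does not contribute
  f1 <- impact_force(m, 1.5, 0.05, 80, 90, g = 9.81)$F_i
  f2 <- impact_force(m, 1.5, 0.05, 80, 90, g = 20)$F_i
  expect_identical(f1, f2)
  # v -> 0 on a horizontal surface: resting weight
  expect_equal(impact_force(m, 0, 0.05, 45, 0)$F_i, m * 9.81, tolerance = 1e-15)
  # strictly increasing in v, decreasing in T at fixed angle on the horizontal
  vs <- seq(0.5, 3, by = 0.5)
  Fv <- vapply(vs, function(v) impact_force(m, v, 0.03, 60, 0)$F_i, 1)
  expect_true(all(diff(Fv) > 0))
  Ts <- seq(0.01, 0.1, by = 0.01)
  FT <- vapply(Ts, function(T) impact_force(m, 1.7, T, 60, 0)$F_i, 1)
  expect_true(all(diff(FT) < 0))
  # lower bound: F_i >= m g cos(phi)
  set.seed(2)
  for (i in 1:50) {
    r <- impact_force(m, runif(1, 0, 3), runif(1, 0.01, 0.1),
                      runif(1, 0, 180), runif(1, 0, 90))
    expect_gte(r$F_i, r$gravitational_term - 1e-12)
  }
})

test_that("adhesion scaling follows the log-log power law", {
  expect_equal(predicted_adhesion(1), 10^(-0.69), tolerance = 1e-12)
  expect_equal(predicted_adhesion(42.55), 10, tolerance = 0.05)
  expect_equal(predicted_adhesion(80) / predicted_adhesion(40), 2^1.041,
               tolerance = 1e-12)
  expect_error(predicted_adhesion(-1), "positive")
})

test_that("safety factor is the adhesion-to-demand ratio", {
  expect_equal(safety_factor(10, 2.5), 4)
  expect_equal(safety_factor(3, 3), 1)
  F <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(safety_factor(10, F)) < 0))
  expect_error(safety_factor(10, 0), "positive")
})
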