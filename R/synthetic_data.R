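#' Treatment presets for the jump simulator
#'
#' Default per-treatment simulation parameters. The landing-phase ground
#' truths (contact speed, landing duration, peak deceleration, maximum body
#' curvature, landing head angle) default to the published treatment means
#' for crested geckos landing on horizontal, 45-degree and vertical
#' platforms; the platform heights and gap distances are the experimental
#' setup values. Incidence angles are not reported per treatment and are
#' fixed conventions here (near-perpendicular on the vertical platform, a
#' steep descent otherwise).
#'
#' @return Named list of preset parameter lists (`horizontal`, `inclined`,
#'   `vertical`).
#' @export
treatment_presets <- function() {
  list(
    horizontal = list(phi = 0, h_to = 0.520, h_l = 0.260, d = 0.435,
                      contact_speed = 1.75, landing_duration = 0.0177,
                      peak_deceleration = 1019, max_curvature = 0.29,
                      landing_angle = 30.2, incidence_angle = 55,
                      contact_marker = "tail_base"),
    inclined = list(phi = 45, h_to = 0.520, h_l = 0.583, d = 0.235,
                    contact_speed = 1.81, landing_duration = 0.0446,
                    peak_deceleration = 449, max_curvature = 0.35,
                    landing_angle = 26.8, incidence_angle = 45,
                    contact_marker = "snout"),
    vertical = list(phi = 90, h_to = 0.528, h_l = 0.428, d = 0.255,
                    contact_speed = 1.66, landing_duration = 0.0697,
                    peak_deceleration = 120, max_curvature = 0.51,
                    landing_angle = 35.0, incidence_angle = 85,
                    contact_marker = "snout")
  )
}

#' Build a simulation configuration
#'
#' Parameters of one simulated jump-and-land trial. Defaults come from the
#' named treatment preset (see [treatment_presets()]); any field can be
#' overridden.
#'
#' @param preset `"horizontal"`, `"inclined"` or `"vertical"`.
#' @param ... Overrides for preset fields, plus: `mass` (kg, default
#'   0.04255, the midpoint of the study's body-mass range), `svl`
#'   (snout to tail-base chord length, m, default 0.1206, the midpoint of
#'   the study's snout-vent-length range), `fps` (default 2000),
#'   `noise_sd` (digitization noise sd in m, default 5e-4),
#'   `net_rotation` (deg of nose-up head rotation over the aerial phase,
#'   default 5), `residual_speed` (post-impact creep speed, m/s, default
#'   0.1), `standoff` (belly clearance at closest approach, m, default
#'   0.002), `g` (default 9.81), `seed` (integer or NULL).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(preset = c("horizontal", "inclined", "vertical"), ...) {
  preset <- match.arg(preset)
  cfg <- treatment_presets()[[preset]]
  cfg$preset <- preset
  cfg$mass <- 0.04255
  cfg$svl <- 0.1206
  cfg$fps <- 2000
  cfg$noise_sd <- 5e-4
  cfg$net_rotation <- 5
  cfg$residual_speed <- 0.1
  cfg$standoff <- 0.002
  cfg$g <- 9.81
  cfg$seed <- NULL
  dots <- list(...)
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(contact_speed > 0, landing_duration > 0, peak_deceleration > 0,
              max_curvature >= 0, mass > 0, svl > 0, fps > 0, noise_sd >= 0,
              residual_speed > 0, residual_speed < contact_speed)
  })
  structure(cfg, class = "simulation_config")
}

# cumulative trapezoid integral of y over x, starting at 0
cumtrap <- function(x, y) {
  c(0, cumsum((y[-length(y)] + y[-1]) / 2 * diff(x)))
}

#' Simulate one jump-and-land trial
#'
#' Forward model with exact ground truth. The belly follows projectile
#' motion (y down, gravity +y) that meets the landing plane with the
#' configured contact speed and incidence angle; after contact its speed
#' magnitude decays through a raised-cosine deceleration pulse whose peak
#' equals the configured peak deceleration, down to a small residual creep
#' speed, while the direction of motion rotates smoothly from the incidence
#' angle to surface-parallel at exactly the configured landing duration (so
#' the closest approach of the belly defines the landing end). Snout and
#' tail-base markers sit on a rigid chord of length `svl` through the belly,
#' oriented so the designated contact marker touches the plane exactly at
#' first contact; during landing the chord is displaced perpendicular to
#' itself so that the deflection-to-chord ratio follows a smooth bow peaking
#' at the configured maximum curvature at the landing end. The eye marker is
#' placed so the snout-eye head angle ramps linearly over the aerial phase
#' to the configured landing angle. Marker placement is kinematic: it
#' realizes every ground-truth metric exactly, at the cost of postural
#' realism. Gaussian noise of sd `noise_sd` is added independently per
#' coordinate and frame.
#'
#' @param config A [simulation_config()].
#' @return List with `trial` (a [trial_recording()]), `truth` (named list of
#'   ground-truth values, including the impact force evaluated on the true
#'   inputs), and `geom` (the landing [platform_geometry()]).
#' @export
simulate_jump <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  dt <- 1 / cf$fps
  Tl <- cf$landing_duration
  V0 <- cf$contact_speed
  vend <- cf$residual_speed
  arad <- cf$incidence_angle * pi / 180
  tau <- pi * (V0 - vend) / (2 * cf$peak_deceleration)
  if (tau >= 0.95 * Tl) {
    stop("peak deceleration too small to stop within the landing duration",
         call. = FALSE)
  }
  if (Tl < 2 * dt) stop("landing duration shorter than 2 frames", call. = FALSE)

  geom <- platform_geometry(cf$phi, anchor = c(0, 0),
                            h_to = cf$h_to, h_l = cf$h_l, d = cf$d)
  hu <- geom$h[1:2] / sqrt(sum(geom$h[1:2]^2))
  ev <- geom$e[1:2]
  s_sign <- if (cf$phi >= 90) -1 else 1
  mhat <- -s_sign * ev                       # unit normal on the approach side
  v_c <- V0 * (cos(arad) * hu + s_sign * sin(arad) * ev)

  # landing-phase speed magnitude and direction angle relative to the plane
  Vfun <- function(t) ifelse(t < tau, vend + (V0 - vend) / 2 * (1 + cos(pi * t / tau)), vend)
  bfun <- function(t) arad * cos(pi * t / (2 * Tl))

  t_land_total <- Tl + max(0.5 * Tl, 0.025)
  n_land <- floor(t_land_total / dt)
  grid <- seq(0, n_land * dt, by = dt / 10)
  Vg <- Vfun(grid)
  bg <- bfun(grid)
  cumP <- cumtrap(grid, Vg * cos(bg))        # in-plane travel
  cumN <- cumtrap(grid, Vg * sin(bg))        # travel toward the plane
  perp_travel <- stats::approx(grid, cumN, Tl)$y
  n0 <- cf$standoff + perp_travel            # belly stand-off at first contact
  if (2 * n0 / cf$svl > 1) {
    stop("belly stand-off at contact exceeds half the body chord", call. = FALSE)
  }

  tl <- (0:n_land) * dt
  Pl <- stats::approx(grid, cumP, tl)$y
  Nl <- n0 - stats::approx(grid, cumN, tl)$y

  # body chord orientation: contact marker exactly on the plane at t0
  k <- 2 * n0 / cf$svl
  normal_comp <- if (identical(cf$contact_marker, "snout")) -k else k
  in_plane_sign <- if (cf$phi >= 90) -1 else 1
  u_b <- in_plane_sign * sqrt(1 - k^2) * hu + normal_comp * mhat

  # flight: backward ballistics from the contact state
  gvec <- c(0, cf$g)
  t_f <- if (abs(v_c[1]) > 0.3) min(0.2, 0.9 * cf$d / abs(v_c[1])) else 0.15
  n_flight <- max(2L, round(t_f / dt))
  t_f <- n_flight * dt

  contact_pt <- geom$anchor + 0.10 * hu
  belly_c <- contact_pt + n0 * mhat
  sback <- (n_flight:1) * dt
  belly_flight <- cbind(belly_c[1] - v_c[1] * sback + 0.5 * gvec[1] * sback^2,
                        belly_c[2] - v_c[2] * sback + 0.5 * gvec[2] * sback^2)
  belly_land <- cbind(contact_pt[1] + hu[1] * Pl + mhat[1] * Nl,
                      contact_pt[2] + hu[2] * Pl + mhat[2] * Nl)
  belly <- rbind(belly_flight, belly_land)
  n_total <- nrow(belly)
  t0_frame <- n_flight                       # 0-based frame of first contact

  # chord bow: belly deflects toward the plane relative to the chord; the
  # displacement is along the chord normal so the measured perpendicular
  # deflection equals the prescribed one exactly
  tprime <- c(rep(-1, n_flight), tl)
  qdef <- ifelse(tprime >= 0,
                 cf$max_curvature * cf$svl * pmax(0, sin(pi * tprime / (2 * Tl))), 0)
  w <- mhat - sum(mhat * u_b) * u_b
  nchord <- w / sqrt(sum(w^2))
  chord_centre <- belly + outer(qdef, nchord)
  half <- (cf$svl / 2) * u_b
  snout <- sweep(chord_centre, 2, half, "+")
  tail <- sweep(chord_centre, 2, half, "-")

  # head angle ramps over the aerial phase, frozen after contact
  takeoff_angle <- cf$landing_angle - cf$net_rotation
  frac <- pmin(1, (0:(n_total - 1L)) / t0_frame)
  gdeg <- takeoff_angle + cf$net_rotation * frac
  grad <- gdeg * pi / 180
  eye_off <- 0.12 * cf$svl
  eye <- snout + eye_off * cbind(cos(grad), sin(grad))

  if (!is.null(cf$seed)) set.seed(cf$seed)
  addnoise <- function(p) {
    if (cf$noise_sd > 0) p + matrix(stats::rnorm(length(p), 0, cf$noise_sd), ncol = 2) else p
  }
  tracks <- list(
    snout = marker_track("snout", addnoise(snout), dt),
    eye = marker_track("eye", addnoise(eye), dt),
    belly = marker_track("belly", addnoise(belly), dt),
    tail_base = marker_track("tail_base", addnoise(tail), dt)
  )
  trial <- trial_recording(tracks,
                           individual_id = cf$individual_id %||% "sim",
                           mass = cf$mass, treatment = cf$phi, fps = cf$fps,
                           trial_id = cf$trial_id %||% sprintf("sim_%s", cf$preset),
                           takeoff_frame = 0L)
  v_to <- v_c - gvec * t_f
  truth <- list(
    t0_frame = t0_frame, t0_s = t0_frame * dt,
    landing_duration = Tl,
    landing_end_frame = t0_frame + round(Tl / dt),
    contact_speed = V0,
    incidence_angle = cf$incidence_angle,
    v_perp = V0 * sin(arad),
    peak_deceleration = cf$peak_deceleration,
    max_curvature = cf$max_curvature,
    landing_angle = cf$landing_angle,
    takeoff_angle = takeoff_angle,
    net_rotation = cf$net_rotation,
    takeoff_speed = sqrt(sum(v_to^2)),
    height_drop = belly_c[2] - belly_flight[1, 2],
    mass = cf$mass, phi = cf$phi,
    contact_marker = cf$contact_marker,
    impact_force = cf$mass * (V0 / Tl) * sin(arad) +
      cf$mass * cf$g * cos(cf$phi * pi / 180)
  )
  list(trial = trial, truth = truth, geom = geom)
}

jitter_lognormal <- function(x, cv) {
  if (cv <= 0) return(x)
  sdl <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -sdl^2 / 2, sdl))
}

#' Simulate a full study
#'
#' Generates `n_individuals x length(presets) x n_trials` trials. Each
#' individual draws a body mass uniformly from the study's 35.9-49.2 g range
#' and a snout-to-tail chord from the 11.37-12.74 cm snout-vent-length
#' range; each trial jitters the strictly positive landing ground truths
#' log-normally with coefficient of variation `jitter_cv` and the angles
#' normally (sd 3 degrees for the landing angle, 2 degrees for incidence and
#' net rotation). With `out_dir` set, trajectory files, per-trial
#' ground-truth JSON sidecars and a `manifest.csv` are written.
#'
#' @param presets Character vector of preset names (default all three).
#' @param n_individuals Number of individuals (default 4).
#' @param n_trials Trials per individual and treatment (default 3).
#' @param seed Integer seed controlling every random draw.
#' @param jitter_cv Trial-to-trial CV of the positive ground truths
#'   (default 0.1; 0 disables jitter).
#' @param noise_sd Marker noise sd in metres (default 5e-4).
#' @param out_dir Optional output directory.
#' @return List with `sims` (list of [simulate_jump()] results), `truths`
#'   (data frame of ground truths) and `manifest` (data frame; has a `file`
#'   column when files were written).
#' @export
simulate_study <- function(presets = c("horizontal", "inclined", "vertical"),
                           n_individuals = 4, n_trials = 3, seed = 1,
                           jitter_cv = 0.1, noise_sd = 5e-4, out_dir = NULL) {
  stopifnot(n_individuals >= 1, n_trials >= 1)
  set.seed(seed)
  masses <- stats::runif(n_individuals, 0.0359, 0.0492)
  svls <- stats::runif(n_individuals, 0.1137, 0.1274)
  n_total <- n_individuals * length(presets) * n_trials
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sims <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_len(n_individuals)) {
    for (pr in presets) {
      base <- treatment_presets()[[pr]]
      for (j in seq_len(n_trials)) {
        idx <- idx + 1L
        id <- sprintf("gecko%d", i)
        tid <- sprintf("%s_%s_t%d", id, pr, j)
        cfg <- simulation_config(
          pr,
          mass = masses[i], svl = svls[i],
          contact_speed = jitter_lognormal(base$contact_speed, jitter_cv),
          landing_duration = jitter_lognormal(base$landing_duration, jitter_cv),
          peak_deceleration = jitter_lognormal(base$peak_deceleration, jitter_cv),
          max_curvature = jitter_lognormal(base$max_curvature, jitter_cv),
          landing_angle = base$landing_angle +
            (if (jitter_cv > 0) stats::rnorm(1, 0, 3) else 0),
          incidence_angle = min(175, max(5, base$incidence_angle +
            (if (jitter_cv > 0) stats::rnorm(1, 0, 2) else 0))),
          net_rotation = 5 + (if (jitter_cv > 0) stats::rnorm(1, 0, 2) else 0),
          noise_sd = noise_sd,
          seed = trial_seeds[idx],
          individual_id = id, trial_id = tid
        )
        sim <- simulate_jump(cfg)
        sims[[tid]] <- sim
        row <- data.frame(trial_id = tid, individual_id = id, preset = pr,
                          treatment = base$phi, mass_kg = masses[i],
                          as.data.frame(sim$truth[c(
                            "t0_frame", "landing_duration", "contact_speed",
                            "incidence_angle", "v_perp", "peak_deceleration",
                            "max_curvature", "landing_angle", "takeoff_speed",
                            "impact_force")]),
                          stringsAsFactors = FALSE)
        if (!is.null(out_dir)) {
          write_trial(sim$trial, file.path(out_dir, paste0(tid, ".csv")))
          jsonlite::write_json(sim$truth, file.path(out_dir, paste0(tid, "_truth.json")),
                               auto_unbox = TRUE, digits = NA)
          row$file <- paste0(tid, ".csv")  # relative to the manifest
        }
        rows[[idx]] <- row
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(sims = sims, truths = manifest, manifest = manifest)
}
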