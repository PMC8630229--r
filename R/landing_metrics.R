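#' Detect first surface contact
#'
#' Returns the 0-based frame index of first contact with the landing surface
#' and the contacting part. A manual annotation on the trial always takes
#' precedence (manual digitization can see limbs that the three-marker set
#' cannot). Otherwise, contact is the first frame at which any tracked
#' marker's perpendicular distance to the platform plane is at most
#' `epsilon`; the part is then that marker's name (forelimb/hindlimb contact
#' cannot be distinguished automatically from snout/belly/tail-base markers).
#' The eye marker is excluded from detection: it measures head orientation
#' and is not a contact surface.
#'
#' @param trial A [trial_recording()] (tracks are used as supplied; pass
#'   smoothed tracks for noise robustness).
#' @param geom The landing [platform_geometry()].
#' @param epsilon Contact threshold in metres (> 0), default 0.002.
#' @return List with `frame` (0-based) and `part`.
#' @export
detect_first_contact <- function(trial, geom, epsilon = 0.002) {
  stopifnot(inherits(trial, "trial_recording"), epsilon > 0)
  if (!is.null(trial$first_contact_frame)) {
    return(list(frame = as.integer(trial$first_contact_frame),
                part = trial$first_contact_part %||% NA_character_))
  }
  contact_markers <- setdiff(names(trial$tracks), "eye")
  dists <- sapply(trial$tracks[contact_markers],
                  function(tr) plane_distance(tr$positions, geom))
  hit <- dists <= epsilon
  rows <- which(rowSums(hit) > 0)
  if (length(rows) == 0L) {
    stop(sprintf("no marker ever comes within %g m of the landing plane", epsilon),
         call. = FALSE)
  }
  r <- rows[1]
  marker <- colnames(dists)[which.min(dists[r, ])]
  list(frame = r - 1L, part = marker)
}

#' Landing duration
#'
#' Time between first contact and the body's closest approach to the
#' substrate, operationalized as the argmin over frames at or after `t0` of
#' the belly's perpendicular distance to the platform plane (earliest frame
#' on ties). The landing-end frame is returned for windowing other metrics.
#'
#' @param trial A [trial_recording()] (smoothed tracks recommended).
#' @param geom The landing [platform_geometry()].
#' @param t0 First-contact frame, 0-based.
#' @return List with `T` (duration, s) and `end_frame` (0-based).
#' @export
landing_duration <- function(trial, geom, t0) {
  stopifnot(inherits(trial, "trial_recording"))
  belly <- trial$tracks$belly
  n <- n_frames(belly)
  if (t0 < 0 || t0 > n - 2L) stop("t0 outside track", call. = FALSE)
  d <- plane_distance(belly$positions[(t0 + 1L):n, , drop = FALSE], geom)
  imin <- which.min(d)  # which.min returns the earliest minimum
  if (imin == length(d)) {
    stop("truncated landing: belly still approaching the surface at the last frame",
         call. = FALSE)
  }
  end_frame <- as.integer(t0 + imin - 1L)
  list(T = (end_frame - t0) * belly$dt, end_frame = end_frame)
}

#' Head angle at a frame
#'
#' Signed angle in degrees between the horizontal and the snout-to-eye line;
#' positive values mean the snout is above the eye (nose up). Evaluated at
#' first contact this is the landing angle; at last take-off contact, the
#' take-off angle. Returns `NA` with a warning if the eye marker is absent.
#'
#' @param trial A [trial_recording()].
#' @param frame 0-based frame index.
#' @return Angle in degrees in (-90, 90], or `NA_real_` if unavailable.
#' @export
head_angle <- function(trial, frame) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(trial$tracks$eye)) {
    warning("eye marker missing: head angle unavailable")
    return(NA_real_)
  }
  sn <- trial$tracks$snout$positions
  ey <- trial$tracks$eye$positions
  if (frame < 0 || frame > nrow(sn) - 1L) stop("frame outside track", call. = FALSE)
  i <- frame + 1L
  dx <- ey[i, 1] - sn[i, 1]
  dy <- ey[i, 2] - sn[i, 2]  # y is down: positive when snout above eye
  unname(atan2(dy, abs(dx)) * 180 / pi)
}

#' Aerial rotation of the head axis
#'
#' Head angle per frame across the aerial window and the net rotation
#' `angle(first contact) - angle(take-off)`. By construction the landing
#' angle equals the take-off angle plus the net rotation.
#'
#' @param trial A [trial_recording()].
#' @param window Length-2 0-based frame vector `c(takeoff_frame, t0)`.
#' @return List with `angles` (deg, one per frame of the window), `frames`,
#'   and `net` (deg).
#' @export
aerial_rotation <- function(trial, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  frames <- window[1]:window[2]
  angles <- vapply(frames, function(f) head_angle(trial, f), 1)
  list(frames = frames, angles = angles,
       net = angles[length(angles)] - angles[1])
}

#' Body curvature series
#'
#' Per frame, `p` is the chord length from snout to tail base and `q` the
#' perpendicular deflection of the belly from that chord; curvature is the
#' dimensionless, scale-free ratio `q/p`. The maximum over the supplied
#' landing window is reported. Frames whose chord is degenerate
#' (`p < 1e-4` m) are skipped with a warning.
#'
#' @param trial A [trial_recording()].
#' @param window Length-2 0-based frame vector over which `max_curvature` is
#'   taken (the full series is computed for all frames).
#' @return A `curvature_series`: list with `frame`, `q`, `p`, `curvature`,
#'   `max_curvature`, `max_frame`.
#' @export
body_curvature <- function(trial, window = NULL) {
  stopifnot(inherits(trial, "trial_recording"))
  sn <- trial$tracks$snout$positions
  be <- trial$tracks$belly$positions
  tb <- trial$tracks$tail_base$positions
  chord <- tb - sn
  p <- sqrt(chord[, 1]^2 + chord[, 2]^2)
  rel <- be - sn
  q <- abs(chord[, 1] * rel[, 2] - chord[, 2] * rel[, 1]) / pmax(p, .Machine$double.eps)
  curv <- q / p
  bad <- p < 1e-4
  if (any(bad)) {
    warning(sprintf("%d frame(s) with degenerate snout-tail chord skipped", sum(bad)))
    curv[bad] <- NA_real_
  }
  n <- nrow(sn)
  frame <- 0:(n - 1L)
  if (is.null(window)) window <- c(0L, n - 1L)
  inw <- frame >= window[1] & frame <= window[2]
  cw <- curv[inw]
  if (all(is.na(cw))) stop("no valid curvature frames in window", call. = FALSE)
  imax <- which.max(cw)
  structure(list(frame = frame, q = q, p = p, curvature = curv,
                 max_curvature = cw[imax],
                 max_frame = frame[inw][imax]),
            class = "curvature_series")
}

#' Last take-off contact frame
#'
#' The last frame at which the tail-base marker (hindlimb proxy) lies within
#' `epsilon` of the take-off plane. Increasing `epsilon` can only move the
#' detected frame later (monotone).
#'
#' @param trial A [trial_recording()].
#' @param takeoff_geom [platform_geometry()] of the take-off platform.
#' @param epsilon Distance threshold (m).
#' @return 0-based frame index.
#' @export
detect_last_takeoff_contact <- function(trial, takeoff_geom, epsilon = 0.002) {
  stopifnot(inherits(trial, "trial_recording"), epsilon > 0)
  d <- plane_distance(trial$tracks$tail_base$positions, takeoff_geom)
  hits <- which(d <= epsilon)
  if (length(hits) == 0L) {
    stop(sprintf("tail_base never within %g m of the take-off plane", epsilon),
         call. = FALSE)
  }
  hits[length(hits)] - 1L
}

#' Take-off speed
#'
#' Smoothed belly speed at the frame of last contact with the take-off
#' substrate (annotated on the trial, or detected with
#' [detect_last_takeoff_contact()]).
#'
#' @param trial A [trial_recording()] whose tracks are already smoothed.
#' @param last_contact_frame 0-based frame of last take-off contact.
#' @return Speed in m/s.
#' @export
takeoff_velocity <- function(trial, last_contact_frame) {
  belly <- trial$tracks$belly
  n <- n_frames(belly)
  f <- as.integer(last_contact_frame)
  if (f < 0 || f > n - 2L) stop("last-contact frame outside track", call. = FALSE)
  ser <- compute_velocity(belly)
  ser$v[f + 1L]
}

#' Smooth all tracks of a trial
#'
#' Applies [smooth_track()] to every marker of the trial with shared
#' settings, returning a trial of identical structure.
#'
#' @param trial A [trial_recording()].
#' @param settings Smoothing settings (see [smooth_track()]).
#' @return A `trial_recording` with smoothed tracks.
#' @export
smooth_trial <- function(trial, settings = list(method = "gcv")) {
  out <- trial
  out$tracks <- lapply(trial$tracks, smooth_track, settings = settings)
  out
}

#' Analyze one landing trial
#'
#' Runs the full per-trial pipeline: smooth tracks, detect first contact and
#' landing end, then compute landing angle, take-off angle and net aerial
#' rotation (when an eye marker and take-off frame are available), maximum
#' body curvature, peak belly deceleration, the landing velocity vector with
#' its incidence angle, and the projected impact force.
#'
#' @param trial A [trial_recording()].
#' @param geom The landing [platform_geometry()].
#' @param config An [analysis_config()].
#' @return One-row data frame with the summary schema of [write_summary()].
#' @export
analyze_trial <- function(trial, geom, config = analysis_config()) {
  stopifnot(inherits(trial, "trial_recording"),
            inherits(geom, "platform_geometry"))
  sm <- smooth_trial(trial, config$smoothing)
  contact <- detect_first_contact(sm, geom, config$epsilon)
  t0 <- contact$frame
  land <- landing_duration(sm, geom, t0)
  win <- c(t0, land$end_frame)

  have_eye <- !is.null(sm$tracks$eye)
  gamma <- if (have_eye) head_angle(sm, t0) else NA_real_
  tko_frame <- trial$takeoff_frame
  tko_angle <- if (have_eye && !is.null(tko_frame)) head_angle(sm, tko_frame) else NA_real_
  net_rot <- if (!is.na(gamma) && !is.na(tko_angle)) gamma - tko_angle else NA_real_
  tko_speed <- if (!is.null(tko_frame)) takeoff_velocity(sm, tko_frame) else NA_real_

  curv <- body_curvature(sm, win)
  ser <- compute_acceleration(compute_velocity(sm$tracks$belly))
  peak_dec <- suppressWarnings(
    if (land$end_frame - t0 >= 2L) as.numeric(max_deceleration(ser, win)) else NA_real_
  )

  vvec <- landing_velocity_vector(sm$tracks$belly, t0)
  v <- sqrt(sum(vvec^2))
  alpha <- incidence_angle(vvec, geom)
  imp <- impact_force(m = trial$mass, v = v, T = land$T, alpha = alpha,
                      phi = geom$phi, g = config$g)

  data.frame(
    trial_id = trial$trial_id,
    individual_id = trial$individual_id,
    treatment = trial$treatment,
    mass_kg = trial$mass,
    t0_s = t0 * sm$tracks$belly$dt,
    t0_frame = t0,
    landing_end_frame = land$end_frame,
    landing_duration_s = land$T,
    landing_angle_deg = gamma,
    takeoff_angle_deg = tko_angle,
    net_rotation_deg = net_rot,
    takeoff_speed_ms = tko_speed,
    max_curvature = curv$max_curvature,
    peak_deceleration_ms2 = peak_dec,
    landing_speed_ms = v,
    incidence_angle_deg = alpha,
    v_perp_ms = imp$v_perp,
    impact_force_n = imp$F_i,
    first_contact_part = contact$part %||% NA_character_,
    stringsAsFactors = FALSE
  )
}
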