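MARKER_NAMES <- c("snout", "eye", "belly", "tail_base")
REQUIRED_MARKERS <- c("snout", "belly", "tail_base")

#' Single-marker trajectory
#'
#' One digitized marker's time series of 2-D positions. Coordinates are in
#' metres in the analysis frame (x horizontal, y vertical increasing
#' downward); the frame interval `dt` is `1/fps` seconds. Frames are
#' contiguous: a gap in the digitized window is a read-time error, not a
#' property a track can have.
#'
#' @param marker_name One of `"snout"`, `"eye"`, `"belly"`, `"tail_base"`.
#' @param positions Numeric matrix (n x 2) of `(x, y)` in metres, n >= 2.
#' @param dt Frame interval in seconds (> 0).
#' @return A `marker_track` object.
#' @export
marker_track <- function(marker_name, positions, dt) {
  marker_name <- match.arg(marker_name, MARKER_NAMES)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("`positions` must have two columns (x, y)", call. = FALSE)
  if (nrow(positions) < 2L) stop("a marker track needs at least 2 positions", call. = FALSE)
  if (!all(is.finite(positions))) {
    stop(sprintf("non-finite coordinates in marker '%s'", marker_name), call. = FALSE)
  }
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(list(marker_name = marker_name, positions = positions, dt = dt),
            class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track '%s': %d frames, dt = %g s>\n",
              x$marker_name, nrow(x$positions), x$dt))
  invisible(x)
}

n_frames <- function(track) nrow(track$positions)

#' One recorded jump trial
#'
#' Bundles the marker tracks of a single jump with its metadata. The snout,
#' belly and tail-base markers are required; the eye marker (used for head
#' angle) is optional. All tracks must have equal length and identical `dt`.
#'
#' @param tracks Named list of [marker_track()] objects keyed by marker name.
#' @param individual_id Identifier of the animal.
#' @param mass Body mass in kg (> 0).
#' @param treatment Landing-surface incline label; numeric degrees (0, 45, 90
#'   by convention, arbitrary allowed).
#' @param fps Recording frame rate in Hz (> 0).
#' @param trial_id Optional trial label.
#' @param first_contact_frame Optional 0-based frame annotation of first
#'   surface contact; takes precedence over automatic detection.
#' @param first_contact_part Optional annotation, one of `"snout"`,
#'   `"forelimb"`, `"belly"`, `"hindlimb"`.
#' @param takeoff_frame Optional 0-based frame of last take-off contact.
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(tracks, individual_id, mass, treatment, fps,
                            trial_id = NA_character_,
                            first_contact_frame = NULL,
                            first_contact_part = NULL,
                            takeoff_frame = NULL) {
  stopifnot(is.list(tracks))
  if (is.null(names(tracks)) || !all(vapply(tracks, inherits, TRUE, "marker_track"))) {
    stop("`tracks` must be a named list of marker_track objects", call. = FALSE)
  }
  missing <- setdiff(REQUIRED_MARKERS, names(tracks))
  if (length(missing) > 0L) {
    stop(sprintf("required marker(s) missing from trial: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lens <- vapply(tracks, n_frames, 1L)
  dts <- vapply(tracks, function(t) t$dt, 1)
  if (length(unique(lens)) != 1L) stop("all marker tracks must have equal length", call. = FALSE)
  if (diff(range(dts)) > 1e-12) stop("all marker tracks must share one dt", call. = FALSE)
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  stopifnot(is.numeric(fps), length(fps) == 1L, is.finite(fps), fps > 0)
  if (!is.null(first_contact_part)) {
    first_contact_part <- match.arg(first_contact_part,
                                    c("snout", "forelimb", "belly", "hindlimb"))
  }
  structure(list(
    tracks = tracks,
    individual_id = as.character(individual_id),
    mass = mass,
    treatment = as.numeric(treatment),
    fps = fps,
    trial_id = as.character(trial_id),
    first_contact_frame = first_contact_frame,
    first_contact_part = first_contact_part,
    takeoff_frame = takeoff_frame
  ), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording %s: individual %s, %g deg, %.1f g, %d frames @ %g fps>\n",
    x$trial_id, x$individual_id, x$treatment, x$mass * 1000,
    n_frames(x$tracks[[1]]), x$fps))
  invisible(x)
}

#' Analysis configuration
#'
#' Tunable settings shared by the pipeline stages.
#'
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @param epsilon Contact-detection distance threshold in metres
#'   (default 0.002, roughly the toe-pad scale).
#' @param smoothing List with elements `method` (`"gcv"` or `"fixed"`),
#'   `lambda` (penalty used when `method = "fixed"`), and optional `k`
#'   (basis dimension; default chosen from track length).
#' @param seed Optional integer seed for stochastic steps.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(g = 9.81, epsilon = 0.002,
                            smoothing = list(method = "gcv", lambda = NULL, k = NULL),
                            seed = NULL) {
  stopifnot(g > 0, epsilon > 0)
  smoothing$method <- match.arg(smoothing$method %||% "gcv", c("gcv", "fixed"))
  structure(list(g = g, epsilon = epsilon, smoothing = smoothing, seed = seed),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file mirrors the fields of [analysis_config()]; missing fields take
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [analysis_config()] object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  analysis_config(
    g = raw$g %||% 9.81,
    epsilon = raw$epsilon %||% 0.002,
    smoothing = raw$smoothing %||% list(method = "gcv", lambda = NULL, k = NULL),
    seed = raw$seed
  )
}

# parse "# key: value" comment lines of a trajectory file into a named list
parse_trajectory_header <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

unit_scale <- function(units) {
  switch(tolower(units),
         m = 1, cm = 0.01, mm = 0.001,
         stop(sprintf("unknown coordinate units '%s' (use m, cm or mm)", units),
              call. = FALSE))
}

#' Read a trial trajectory file
#'
#' Reads a long-form delimited trajectory file with mandatory header row
#' `frame,time_s,marker,x,y` and `#`-prefixed comment lines carrying metadata
#' (`fps`, `units`, `individual`, `treatment`, `mass_g`, optionally
#' `scale_m_per_unit`, `trial`, `first_contact_frame`, `first_contact_part`,
#' `takeoff_frame`). Coordinates are converted to metres at read time using
#' the declared `units` (m, cm or mm) times any `scale_m_per_unit` calibration
#' factor. Values supplied through `meta` override the file header.
#'
#' @param path Path to the trajectory file.
#' @param meta Optional named list overriding header metadata.
#' @return A validated [trial_recording()].
#' @export
read_trial <- function(path, meta = list()) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  header <- parse_trajectory_header(lines[startsWith(lines, "#")])
  header[names(meta)] <- meta
  for (f in c("fps", "individual", "treatment", "mass_g")) {
    if (is.null(header[[f]])) {
      stop(sprintf("trajectory metadata field '%s' missing (header or `meta`)", f),
           call. = FALSE)
    }
  }
  dat <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                         stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "marker", "x", "y")
  if (!all(need %in% names(dat))) {
    stop(sprintf("trajectory file must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  scale <- unit_scale(header$units %||% "m") * (header$scale_m_per_unit %||% 1)
  fps <- header$fps
  dt <- 1 / fps
  tracks <- list()
  for (mk in unique(dat$marker)) {
    sub <- dat[dat$marker == mk, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (!all(is.finite(sub$x)) || !all(is.finite(sub$y))) {
      stop(sprintf("non-finite coordinates for marker '%s' in %s", mk, path),
           call. = FALSE)
    }
    fr <- sub$frame
    if (nrow(sub) > 1L && any(diff(fr) != 1L)) {
      stop(sprintf("non-uniform frame spacing (missing frames) for marker '%s' in %s",
                   mk, path), call. = FALSE)
    }
    tracks[[mk]] <- marker_track(mk, cbind(sub$x, sub$y) * scale, dt)
  }
  trial_recording(
    tracks,
    individual_id = header$individual,
    mass = header$mass_g / 1000,
    treatment = header$treatment,
    fps = fps,
    trial_id = header$trial %||% basename(path),
    first_contact_frame = header$first_contact_frame,
    first_contact_part = header$first_contact_part,
    takeoff_frame = header$takeoff_frame
  )
}

#' Write a trial to a trajectory file
#'
#' Inverse of [read_trial()]: emits the long-form comma-delimited format with
#' a metadata comment header. Coordinates are written in metres with enough
#' digits that a read/write round trip is the identity to well below 1e-9 m.
#'
#' @param trial A [trial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  hdr <- c(
    "# landkin trajectory v1 (x horizontal, y vertical positive downward, metres)",
    sprintf("# fps: %.10g", trial$fps),
    "# units: m",
    sprintf("# individual: %s", trial$individual_id),
    sprintf("# treatment: %.10g", trial$treatment),
    sprintf("# mass_g: %.10g", trial$mass * 1000),
    sprintf("# trial: %s", trial$trial_id)
  )
  if (!is.null(trial$first_contact_frame)) {
    hdr <- c(hdr, sprintf("# first_contact_frame: %d", as.integer(trial$first_contact_frame)))
  }
  if (!is.null(trial$first_contact_part)) {
    hdr <- c(hdr, sprintf("# first_contact_part: %s", trial$first_contact_part))
  }
  if (!is.null(trial$takeoff_frame)) {
    hdr <- c(hdr, sprintf("# takeoff_frame: %d", as.integer(trial$takeoff_frame)))
  }
  dt <- trial$tracks[[1]]$dt
  rows <- lapply(names(trial$tracks), function(mk) {
    p <- trial$tracks[[mk]]$positions
    n <- nrow(p)
    sprintf("%d,%.*g,%s,%.*g,%.*g", 0:(n - 1L), 12, (0:(n - 1L)) * dt, mk,
            15, p[, 1], 15, p[, 2])
  })
  writeLines(c(hdr, "frame,time_s,marker,x,y", unlist(rows)), path)
  invisible(path)
}

SUMMARY_COLUMNS <- c(
  "trial_id", "individual_id", "treatment", "mass_kg",
  "t0_s", "t0_frame", "landing_end_frame", "landing_duration_s",
  "landing_angle_deg", "takeoff_angle_deg", "net_rotation_deg",
  "takeoff_speed_ms", "max_curvature", "peak_deceleration_ms2",
  "landing_speed_ms", "incidence_angle_deg", "v_perp_ms",
  "impact_force_n", "first_contact_part"
)

#' Write per-trial landing summaries to a CSV file
#'
#' One row per trial holding all derived quantities and metadata. The schema
#' is fixed (see `landkin:::SUMMARY_COLUMNS`) and round-trips through
#' [read_summary()] to better than 1e-9.
#'
#' @param summaries A data frame of landing summaries (rows from
#'   [analyze_trial()]), non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop("`summaries` must be a non-empty data frame of landing summaries",
         call. = FALSE)
  }
  missing <- setdiff(SUMMARY_COLUMNS, names(summaries))
  if (length(missing) > 0L) {
    stop(sprintf("summary is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(summaries[, SUMMARY_COLUMNS], path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write summary file '%s': %s",
                                path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read a landing-summary CSV written by [write_summary()]
#'
#' @param path CSV path.
#' @return Data frame with the summary schema.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop(sprintf("summary file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
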