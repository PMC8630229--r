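#' Smooth a marker track with a quintic penalized spline
#'
#' Smooths the x(t) and y(t) coordinate series of a marker with a degree-5
#' (quintic) penalized B-spline, penalizing the integrated squared third
#' derivative. Both coordinates share a single smoothing penalty chosen by
#' generalized cross-validation (GCV) on the summed residual sum of squares;
#' sharing one penalty makes the smoother rotation- and
#' translation-equivariant, so results do not depend on the orientation of
#' the digitizing frame. A fixed penalty can be supplied instead for exact
#' reproducibility.
#'
#' Everything downstream (speed, acceleration, contact detection, the landing
#' velocity vector) is derived from the smoothed coordinates, so the data are
#' smoothed exactly once per marker.
#'
#' @param track A [marker_track()] with at least 8 frames.
#' @param settings List: `method` (`"gcv"` default, or `"fixed"`), `lambda`
#'   (penalty for `method = "fixed"`), `k` (basis dimension; default
#'   `min(n - 2, max(20, n/3))`).
#' @return A [marker_track()] of identical length and `dt` with smoothed
#'   coordinates; the selected penalty is attached as attribute `"lambda"`.
#'   A degenerate track (all positions identical) is returned unchanged.
#' @export
smooth_track <- function(track, settings = list(method = "gcv")) {
  stopifnot(inherits(track, "marker_track"))
  n <- n_frames(track)
  if (n < 8L) stop("smoothing a track requires at least 8 frames", call. = FALSE)
  pos <- track$positions
  if (max(abs(pos[, 1] - pos[1, 1])) < 1e-12 &&
      max(abs(pos[, 2] - pos[1, 2])) < 1e-12) {
    return(track)  # degenerate: constant position
  }
  method <- settings$method %||% "gcv"
  k <- settings$k %||% min(n - 2L, max(20L, ceiling(n / 3)))
  k <- max(7L, min(k, n - 1L))
  bas <- quintic_basis(n, track$dt, k)
  fit <- if (identical(method, "fixed")) {
    lam <- settings$lambda
    if (is.null(lam) || !is.finite(lam) || lam < 0) {
      stop("`settings$lambda` must be a non-negative number for method = 'fixed'",
           call. = FALSE)
    }
    pspline_fit(bas, pos, lam)
  } else {
    pspline_gcv(bas, pos)
  }
  out <- marker_track(track$marker_name, fit$fitted, track$dt)
  attr(out, "lambda") <- fit$lambda
  out
}

# Degree-5 B-spline basis with third-derivative penalty, evaluated on the
# frame grid. Returns the design matrix and penalty plus cached crossproducts.
quintic_basis <- function(n, dt, k) {
  t <- (seq_len(n) - 1) * dt
  sm <- mgcv::smoothCon(mgcv::s(t, bs = "bs", m = c(5, 3), k = k),
                        data = data.frame(t = t), absorb.cons = FALSE)[[1]]
  X <- sm$X
  S <- sm$S[[1]]
  # scale penalty so lambda is comparable across track lengths
  S <- S * (norm(X, "F")^2 / max(norm(S, "F"), .Machine$double.eps))
  list(X = X, S = S, XtX = crossprod(X), n = n, k = ncol(X))
}

pspline_fit <- function(bas, pos, lambda) {
  # centering keeps the working response small, which keeps the linear-solve
  # rounding error well below the 1e-9 equivariance budget
  mu <- colMeans(pos)
  yc <- sweep(pos, 2, mu)
  A <- bas$XtX + lambda * bas$S
  diag(A) <- diag(A) + 1e-12 * mean(diag(bas$XtX))
  beta <- solve(A, crossprod(bas$X, yc))
  fitted <- sweep(bas$X %*% beta, 2, mu, "+")
  edf <- sum(diag(solve(A, bas$XtX)))
  rss <- sum((yc - bas$X %*% beta)^2)
  list(fitted = fitted, lambda = lambda, edf = edf, rss = rss)
}

# Shared-penalty bivariate GCV: minimize n * RSS_total / (n - edf)^2 over
# log10(lambda). The objective is invariant under rotation of the coordinate
# pair, which is what makes the smoother equivariant.
pspline_gcv <- function(bas, pos) {
  score <- function(loglam) {
    f <- pspline_fit(bas, pos, 10^loglam)
    denom <- max(bas$n - f$edf, 1e-8)
    bas$n * f$rss / denom^2
  }
  opt <- stats::optimize(score, interval = c(-14, 6), tol = 1e-9)
  pspline_fit(bas, pos, 10^opt$minimum)
}

#' Frame-wise speed of a marker track
#'
#' Computes per-frame displacement `s` (the Euclidean distance between
#' consecutive smoothed positions) and speed `v = s/dt`. The result is an
#' unsigned speed (a norm): a marker reversing direction shows a speed
#' minimum, not a sign change. Values are aligned to the earlier frame of
#' each pair (forward differences).
#'
#' @param track A (smoothed) [marker_track()].
#' @return A `kinematic_series` with fields `marker_name`, `frame` (0-based),
#'   `times` (s), `s` (m), `v` (m/s), `dt`; acceleration is added by
#'   [compute_acceleration()].
#' @export
compute_velocity <- function(track) {
  stopifnot(inherits(track, "marker_track"))
  d <- diff(track$positions)
  s <- sqrt(d[, 1]^2 + d[, 2]^2)
  frame <- 0:(nrow(d) - 1L)
  structure(list(marker_name = track$marker_name, frame = frame,
                 times = frame * track$dt, s = s, v = s / track$dt,
                 a = NULL, dt = track$dt),
            class = "kinematic_series")
}

#' Frame-wise acceleration from a speed series
#'
#' Forward finite difference of speed over `dt`, aligned to the earlier
#' frame. Deceleration (decreasing speed) gives negative values.
#'
#' @param series A `kinematic_series` from [compute_velocity()].
#' @return The series with field `a` (m/s^2) and `a_frame` (0-based frames).
#' @export
compute_acceleration <- function(series) {
  stopifnot(inherits(series, "kinematic_series"))
  if (is.null(series$v)) stop("speed series missing", call. = FALSE)
  series$a <- diff(series$v) / series$dt
  series$a_frame <- series$frame[-length(series$frame)]
  series
}

#' Peak deceleration over a frame window
#'
#' Returns `-1` times the most negative acceleration over the window (the
#' convention for reporting maximal deceleration as a positive number). If
#' the series never decelerates in the window the result is non-positive and
#' is flagged with attribute `no_deceleration = TRUE` plus a warning.
#'
#' @param series A `kinematic_series` with acceleration (see
#'   [compute_acceleration()]).
#' @param window Length-2 integer vector of 0-based original frame indices
#'   `c(first, last)`; acceleration values whose three-frame support lies
#'   inside the window are used.
#' @return Scalar m/s^2 with attribute `no_deceleration`.
#' @export
max_deceleration <- function(series, window) {
  stopifnot(inherits(series, "kinematic_series"))
  if (is.null(series$a)) series <- compute_acceleration(series)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  keep <- series$a_frame >= window[1] & (series$a_frame + 2L) <= window[2]
  if (!any(keep)) stop("empty acceleration window", call. = FALSE)
  a <- series$a[keep]
  out <- -min(a)
  flag <- min(a) >= 0
  if (flag) warning("no deceleration in window; peak deceleration is non-positive")
  attr(out, "no_deceleration") <- flag
  out
}
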