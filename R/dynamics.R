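## Unwrapping, drift removal, mean-squared displacement, and the two
## diffusion estimators (fixed-origin linear fit and sliding-window) with
## block-averaged standard errors.

#' Unwrap a periodic trajectory into continuous coordinates
#'
#' Displacement-based scheme: u(0) = w(0) and
#' u(t) = u(t-1) + minimum-image displacement from w(t-1) to w(t), using the
#' current frame's box so that slow box-size changes are handled. Correct
#' whenever no particle moves half a box length between frames; a warning is
#' issued if any inter-frame minimum-image step approaches L/2.
#'
#' @param traj a wrapped [wall_trajectory()].
#' @return the trajectory with continuous coordinates (`wrapped = FALSE`).
#' @export
unwrap_trajectory <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 2) stop("unwrapping needs at least 2 frames")
  xyz <- traj$xyz
  u <- xyz
  warned <- FALSE
  for (f in 2:nf) {
    box <- traj$box[f, ]
    d <- minimum_image_displacement(matrix(xyz[, , f - 1], ncol = 3),
                                    matrix(xyz[, , f], ncol = 3), box)
    if (!warned && any(abs(d) > 0.45 * matrix(box, nrow(d), 3, byrow = TRUE))) {
      warning("inter-frame displacement close to half a box length; ",
              "unwrapping may be unreliable at this frame interval")
      warned <- TRUE
    }
    u[, , f] <- u[, , f - 1] + d
  }
  out <- traj
  out$xyz <- u
  out$wrapped <- FALSE
  out
}

#' Remove the drift of a reference group
#'
#' Translation-only alignment: subtracts the reference group's mass-weighted
#' centre-of-mass displacement (relative to the first frame) from every atom,
#' so the reference COM becomes time-invariant. Used with the central
#' cellulose microfibril as reference to eliminate whole-system drift from
#' thermostat fluctuations. Rotational superposition is deliberately not
#' applied: it would corrupt the MSDs of everything outside the reference.
#'
#' @param traj an unwrapped [wall_trajectory()].
#' @param reference integer atom indices of the reference group.
#' @return the drift-corrected trajectory.
#' @export
remove_reference_drift <- function(traj, reference) {
  if (length(reference) == 0) stop("reference group is empty")
  m <- traj$structure$atoms$mass[reference]
  nf <- n_frames(traj)
  com0 <- NULL
  out <- traj
  for (f in seq_len(nf)) {
    r <- frame_coords(traj, f)[reference, , drop = FALSE]
    com <- colSums(r * m) / sum(m)
    if (f == 1) com0 <- com
    out$xyz[, , f] <- sweep(frame_coords(traj, f), 2, com - com0, "-")
  }
  out
}

#' Fixed-origin mean-squared displacement
#'
#' MSD(t) = <|r(t) - r(t_ref)|^2> averaged over the group members, for all
#' frames at or after the reference time (the first frame after
#' equilibration by default). No time-origin averaging is performed: the
#' reference frame is fixed, matching the water-diffusion protocol.
#'
#' @param traj an unwrapped [wall_trajectory()].
#' @param group integer atom indices.
#' @param t_ref reference time in ns (default: the trajectory's
#'   equilibration cutoff).
#' @return object of class `wall_msd`: data.frame with columns `time`, `lag`
#'   (= time - t_ref) and `msd` (Angstrom^2), plus attributes `n` (group
#'   size) and `t_ref`.
#' @export
msd_fixed_origin <- function(traj, group, t_ref = traj$equilibration) {
  if (length(group) == 0) stop("group is empty")
  tt <- frame_times(traj)
  f_ref <- which(tt >= t_ref)[1]
  if (is.na(f_ref)) stop("t_ref is beyond the last frame")
  frames <- f_ref:n_frames(traj)
  r0 <- frame_coords(traj, f_ref)[group, , drop = FALSE]
  msd <- vapply(frames, function(f) {
    d <- frame_coords(traj, f)[group, , drop = FALSE] - r0
    mean(rowSums(d * d))
  }, numeric(1))
  out <- data.frame(time = tt[frames], lag = tt[frames] - tt[f_ref],
                    msd = msd)
  attr(out, "n") <- length(group)
  attr(out, "t_ref") <- tt[f_ref]
  class(out) <- c("wall_msd", "data.frame")
  out
}

#' Time-origin-averaged mean-squared displacement
#'
#' MSD as a function of lag, averaged over all available time origins as
#' well as group members: MSD(L) = <|r(t0 + L) - r(t0)|^2> over t0. Far
#' better determined than the fixed-origin variant (whose uncertainty is set
#' entirely by the group size at a single origin), at the cost of correlated
#' lag points; this is the variant to use when validating estimators against
#' a known coefficient.
#'
#' @param traj an unwrapped [wall_trajectory()].
#' @param group integer atom indices.
#' @param lags integer vector of lags in frames (default: ~50 lags spanning
#'   up to a tenth of the post-equilibration window; longer lags have too few
#'   independent segments to average over and degrade the fit).
#' @return a `wall_msd` data.frame (columns `time`, `lag`, `msd`).
#' @export
msd_time_averaged <- function(traj, group, lags = NULL) {
  if (length(group) == 0) stop("group is empty")
  tt <- frame_times(traj)
  f0 <- which(tt >= traj$equilibration)[1]
  nf <- n_frames(traj)
  navail <- nf - f0 + 1
  if (is.null(lags)) {
    max_lag <- max(1L, floor(navail / 10))
    lags <- unique(round(seq(1, max_lag, length.out = min(50, max_lag))))
  }
  stopifnot(all(lags >= 1), all(lags < navail))
  msd <- vapply(lags, function(L) {
    starts <- f0:(nf - L)
    tot <- 0
    for (s in starts) {
      d <- frame_coords(traj, s + L)[group, , drop = FALSE] -
        frame_coords(traj, s)[group, , drop = FALSE]
      tot <- tot + mean(rowSums(d * d))
    }
    tot / length(starts)
  }, numeric(1))
  out <- data.frame(time = tt[f0] + lags * traj$dt, lag = lags * traj$dt,
                    msd = msd)
  attr(out, "n") <- length(group)
  attr(out, "t_ref") <- tt[f0]
  class(out) <- c("wall_msd", "data.frame")
  out
}

new_diffusion_estimate <- function(d_a2ns, se_a2ns, estimator, ...) {
  structure(list(d_a2ns = d_a2ns, d_cm2s = d_a2ns * 1e-7,
                 se_a2ns = se_a2ns, se_cm2s = se_a2ns * 1e-7,
                 estimator = estimator, ...),
            class = "wall_diffusion")
}

#' @export
print.wall_diffusion <- function(x, ...) {
  cat(sprintf("D = %.4g cm^2/s (%.4g A^2/ns) +/- %.2g, estimator: %s\n",
              x$d_cm2s, x$d_a2ns, x$se_cm2s, x$estimator))
  invisible(x)
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Least-squares slope of MSD versus elapsed time divided by 6 (3-D Einstein
#' relation). The default fit window spans 10-90% of the available lag range,
#' avoiding both the short-time ballistic/cage regime and the poorly averaged
#' tail.
#'
#' @param msd a [msd_fixed_origin()] result.
#' @param fit_range length-2 fractions of the lag span to fit over, or a
#'   length-2 numeric in ns via `fit_window_ns`.
#' @param fit_window_ns optional explicit lag window in ns (overrides
#'   `fit_range`).
#' @return a `wall_diffusion` estimate (D in cm^2/s and Angstrom^2/ns, slope
#'   standard error, R^2, and the fitted window).
#' @export
diffusion_linear <- function(msd, fit_range = c(0.1, 0.9),
                             fit_window_ns = NULL) {
  lag <- msd$lag
  span <- max(lag)
  win <- if (!is.null(fit_window_ns)) fit_window_ns else fit_range * span
  keep <- lag >= win[1] & lag <= win[2] & lag > 0
  if (sum(keep) < 2) stop("fewer than 2 points in the fit window")
  if (stats::var(lag[keep]) == 0) stop("degenerate (zero-variance) time axis")
  fit <- stats::lm(msd ~ lag, data = msd[keep, ])
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary.lm warning
  slope <- stats::coef(fit)[["lag"]]
  se <- sm$coefficients["lag", "Std. Error"]
  new_diffusion_estimate(slope / 6, se / 6, "linear_fit",
                         r_squared = sm$r.squared, fit_window_ns = win,
                         n_points = sum(keep))
}

#' Diffusion coefficient from sliding displacement windows
#'
#' For every window start t0 (post-equilibration, advancing by `stride`),
#' D_w = <|r(t0 + window) - r(t0)|^2> / (6 * window) averaged over the group;
#' the estimate is the mean over windows. Because overlapping windows are
#' strongly correlated, the standard error is computed from block means over
#' non-overlapping window-length segments, not from the raw window spread.
#'
#' @param traj an unwrapped [wall_trajectory()].
#' @param group integer atom indices.
#' @param window lag time Delta-t in ns (50 in the source protocol).
#' @param stride window-start spacing in ns (default one frame, maximally
#'   overlapping).
#' @return a `wall_diffusion` estimate with the block count used.
#' @export
diffusion_sliding <- function(traj, group, window, stride = traj$dt) {
  if (length(group) == 0) stop("group is empty")
  tt <- frame_times(traj)
  f0 <- which(tt >= traj$equilibration)[1]
  lag_f <- round(window / traj$dt)
  if (lag_f < 1 || f0 + lag_f > n_frames(traj))
    stop("window longer than the post-equilibration trajectory")
  stride_f <- max(1L, round(stride / traj$dt))
  starts <- seq(f0, n_frames(traj) - lag_f, by = stride_f)
  d_w <- vapply(starts, function(s) {
    d <- frame_coords(traj, s + lag_f)[group, , drop = FALSE] -
      frame_coords(traj, s)[group, , drop = FALSE]
    mean(rowSums(d * d)) / (6 * window)
  }, numeric(1))
  block_id <- floor((tt[starts] - tt[f0]) / window)
  bm <- tapply(d_w, block_id, mean)
  se <- if (length(bm) >= 2) stats::sd(bm) / sqrt(length(bm)) else NA_real_
  new_diffusion_estimate(mean(d_w), se, "sliding_window",
                         window_ns = window, n_windows = length(starts),
                         n_blocks = length(bm))
}

#' Block-averaged standard error
#'
#' Splits a series into `n_blocks` contiguous blocks and returns the standard
#' deviation of the block means divided by sqrt(n_blocks). This is the
#' uncertainty convention used throughout: 19 x 50 ns segments for diffusion,
#' 20 equal parts for contact and RDF statistics.
#'
#' @param values numeric series (chronological order).
#' @param n_blocks number of contiguous blocks (>= 2); defaults to
#'   `length(values)` (each value its own block).
#' @return standard error of the mean.
#' @export
#' @examples
#' block_error(c(1, 3))  # sd sqrt(2), se 1
block_error <- function(values, n_blocks = length(values)) {
  if (n_blocks < 2) stop("need at least 2 blocks")
  id <- floor((seq_along(values) - 1) * n_blocks / length(values))
  bm <- tapply(values, id, mean)
  stats::sd(bm) / sqrt(length(bm))
}
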