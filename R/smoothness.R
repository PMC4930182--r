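#' Jerk time series of the moving-side joints
#'
#' Jerk is the third time-derivative of position. The movement vector stacks
#' the six moving-side joints (head, shoulder center, shoulder, elbow, wrist,
#' hand) in three dimensions, so the jerk series is 18-dimensional. It is
#' estimated by three repeated central differences at the sampling rate; each
#' application trims one sample from each end, so the series is 6 samples
#' shorter than the recording and at least 7 frames are required.
#'
#' @param rec A clipped, uniformly sampled [motion_recording()].
#' @return List: `$t` (times of the retained samples), `$jerk`
#'   (`(n-6) x 18` matrix, units length/s^3).
#' @export
jerk_series <- function(rec) {
  stopifnot(inherits(rec, "motion_recording"))
  rec <- resample_uniform(rec)
  n <- n_frames(rec)
  if (n < 7L) stop("insufficient data: jerk needs >= 7 frames, got ", n)
  dt <- 1 / rec$frame_rate
  J <- side_position_matrix(rec)
  for (i in 1:3) J <- central_diff(J, dt)
  list(t = rec$frames$t[4:(n - 3L)], jerk = J)
}

central_diff <- function(m, dt) {
  n <- nrow(m)
  (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) / (2 * dt)
}

#' Dimensionless normalized jerk of a movement
#'
#' The integrated squared jerk scales with movement duration and amplitude,
#' so raw values from different patients are not comparable. Multiplying by
#' duration^5 / length^2 removes both scales; the square root gives a
#' quantity proportional to absolute jerk:
#'
#' \deqn{NJ = \sqrt{\tfrac12 \int_{T_1}^{T_2} \|jerk(t)\|^2\,dt \times
#'   duration^5 / length^2}}
#'
#' where duration is the clipped length `T2 - T1` and length is the maximum
#' distance of the (18-dimensional) position vector from its value at `T1`.
#' A minimum-jerk point-to-point reach attains the floor `sqrt(360)`; tremor
#' and segmented movement raise the score. The statistic is invariant under
#' uniform spatial scaling and uniform time dilation of the trajectory.
#'
#' The squared-jerk integral is evaluated by the trapezoidal rule over the
#' differentiated samples and extended to the full clip window `[T1, T2]` by
#' holding the boundary jerk values constant over the samples the
#' finite-difference stencil trims.
#'
#' @param rec A clipped, uniformly sampled [motion_recording()] (>= 7
#'   frames). Works on raw meters or on pose-normalized coordinates; the
#'   result is dimensionless either way.
#' @param length_joint `"all"` (default): length from the full 18-dimensional
#'   displacement; `"hand"`: hand-joint displacement only.
#' @return A `jerk_result`: list with `duration` (s), `length`,
#'   `integrated_squared_jerk`, `normalized_jerk` and `log_jerk` (log10).
#' @export
normalized_jerk <- function(rec, length_joint = c("all", "hand")) {
  length_joint <- match.arg(length_joint)
  rec <- resample_uniform(rec)
  js <- jerk_series(rec)
  t <- rec$frames$t
  T1 <- t[1L]
  T2 <- t[length(t)]
  duration <- T2 - T1
  P <- if (length_joint == "all") side_position_matrix(rec)
       else joint_xyz(rec, "hand")
  disp <- sweep(P, 2L, P[1L, ])
  len <- sqrt(max(rowSums(disp^2)))
  if (len < 1e-12) stop("degenerate motion: no displacement from T1")
  j2 <- rowSums(js$jerk^2)
  isj <- trapz(js$t, j2) +
    (js$t[1L] - T1) * j2[1L] +
    (T2 - js$t[length(j2)]) * j2[length(j2)]
  nj <- sqrt(0.5 * isj * duration^5 / len^2)
  structure(list(duration = duration, length = len,
                 integrated_squared_jerk = isj,
                 normalized_jerk = nj, log_jerk = log_jerk(nj)),
            class = "jerk_result")
}

#' @export
print.jerk_result <- function(x, ...) {
  cat(sprintf(
    "<jerk_result> duration %.3f s, length %.4f, NJ %.2f (log10 %.3f)\n",
    x$duration, x$length, x$normalized_jerk, x$log_jerk))
  invisible(x)
}

#' Log-transformed jerk score
#'
#' Normalized-jerk scores are strongly right-skewed across a cohort; the
#' base-10 logarithm is used for reporting and statistics.
#'
#' @param j Positive normalized-jerk value(s).
#' @param base Logarithm base (default 10).
#' @return `log(j, base)`.
#' @export
log_jerk <- function(j, base = 10) {
  if (any(j <= 0)) stop("log jerk requires a positive jerk score")
  log(j, base = base)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
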