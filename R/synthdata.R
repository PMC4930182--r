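#' Minimum-jerk point-to-point profile
#'
#' The quintic profile `x(t) = D (10 tau^3 - 15 tau^4 + 6 tau^5)`,
#' `tau = t/T`, is the smooth-reach reference: it minimizes integrated
#' squared jerk among trajectories with rest boundary conditions, reaches
#' peak velocity `1.875 D / T` at mid-movement, and attains the
#' normalized-jerk floor `sqrt(360)`.
#'
#' @param D Total displacement. @param T_total Movement duration, seconds.
#' @param fs Sampling rate, Hz.
#' @return List: `$t` (times from 0 to `T_total` inclusive), `$x` (positions).
#' @export
min_jerk_trajectory <- function(D, T_total, fs) {
  stopifnot(D != 0 || TRUE, T_total > 0, fs > 0)
  t <- seq(0, T_total, by = 1 / fs)
  tau <- t / T_total
  list(t = t, x = D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5))
}

#' Parameters of one synthetic item attempt
#'
#' Encodes the generative model of a single recording: which item, how well
#' it is performed (the score class sets the achieved fraction of the item's
#' full range of motion), how long the reach takes, and how much tremor and
#' sensor jitter corrupt the trace.
#'
#' Amplitude is monotone in the score class by construction: class 0 draws
#' its range fraction from \[0, 0.2\], class 1 from \[0.3, 0.7\], class 2
#' from \[0.8, 1\]. Tremor is band-limited (default 4--10 Hz, inside the
#' 15 Hz Nyquist of 30 Hz sampling). The default tremor and jitter scales
#' are tens of micrometers: they represent residual noise after the
#' tracker's internal smoothing, and are the scale at which unsmoothed
#' third differences at 30 Hz keep the healthy-arm normalized jerk near its
#' minimum-jerk floor.
#'
#' @param item One of [fma_items()]. @param score_class 0, 1 or 2.
#' @param amplitude_fraction Achieved fraction of the item's full range;
#'   `NULL` (default) draws it from the score class band when the motion is
#'   generated.
#' @param duration Reach duration in seconds (default 2).
#' @param tremor_amplitude Tremor RMS amplitude in meters at the hand
#'   (default 5e-5).
#' @param tremor_band Tremor frequency band in Hz (default `c(4, 10)`).
#' @param sensor_noise_sd White sensor-jitter SD in meters (default 2e-5).
#' @param pad Still padding before and after the reach, seconds (default 0.7).
#' @param frame_rate Sampling rate in Hz (default 30).
#' @param side Recorded arm (default `"left"`).
#' @param subject_id Identifier stamped on the recording.
#' @return List of class `motion_params`.
#' @export
motion_params <- function(item, score_class, amplitude_fraction = NULL,
                          duration = 2, tremor_amplitude = 5e-5,
                          tremor_band = c(4, 10), sensor_noise_sd = 2e-5,
                          pad = 0.7, frame_rate = 30, side = "left",
                          subject_id = "synthetic") {
  item <- match_item(item)
  stopifnot(score_class %in% 0:2, duration > 0, tremor_amplitude >= 0,
            sensor_noise_sd >= 0, pad >= 0, frame_rate > 0)
  if (tremor_band[1L] <= 0 || tremor_band[2L] >= frame_rate / 2 ||
      tremor_band[1L] >= tremor_band[2L]) {
    stop("tremor_band must lie within (0, frame_rate/2)")
  }
  structure(list(item = item, score_class = as.integer(score_class),
                 amplitude_fraction = amplitude_fraction, duration = duration,
                 tremor_amplitude = tremor_amplitude,
                 tremor_band = tremor_band,
                 sensor_noise_sd = sensor_noise_sd, pad = pad,
                 frame_rate = frame_rate, side = match_side(side),
                 subject_id = subject_id),
            class = "motion_params")
}

# per-item hand-path direction (unit-normalized below) and full range (m),
# relative to the resting hand, for a left arm facing the camera
item_motion_table <- function() {
  d <- rbind(
    shoulder_retraction                  = c(0.0,  0.3, -1.0, 0.10),
    shoulder_elevation                   = c(0.0,  1.0, -0.2, 0.12),
    shoulder_abduction                   = c(1.0,  0.6,  0.0, 0.35),
    shoulder_external_rotation           = c(0.6,  0.0, -0.8, 0.25),
    elbow_flexion                        = c(-0.6, 0.8, -0.3, 0.55),
    forearm_supination                   = c(0.3,  0.2, -0.2, 0.15),
    shoulder_adduction_internal_rotation = c(-0.8, 0.1,  0.2, 0.30),
    elbow_extension                      = c(0.2, -0.3, -0.9, 0.35),
    forearm_pronation                    = c(0.3, -0.2,  0.2, 0.15),
    hand_to_lumbar_spine                 = c(-0.4, -0.7, 0.4, 0.35),
    shoulder_flexion_0_90                = c(0.0,  0.6, -0.8, 0.45),
    shoulder_abduction_0_90              = c(1.0,  0.7,  0.0, 0.40),
    shoulder_flexion_90_180              = c(0.0,  1.0, -0.3, 0.55))
  colnames(d) <- c("dx", "dy", "dz", "range")
  d
}

# arm segment lengths (m): upper arm, forearm, wrist-to-hand, half shoulder
ARM_SEGMENTS <- c(upper = 0.28, forearm = 0.26, hand = 0.08, half_shoulder = 0.18)

# band-limited tremor: sum of sinusoids with random frequencies and phases,
# scaled to the requested RMS amplitude; draws from the current RNG stream
tremor_series <- function(n, fs, band, rms, k = 6L) {
  if (rms <= 0) return(numeric(n))
  t <- (seq_len(n) - 1L) / fs
  f <- stats::runif(k, band[1L], band[2L])
  ph <- stats::runif(k, 0, 2 * pi)
  a <- stats::rexp(k)
  x <- colSums(a * sin(outer(2 * pi * f, t) + ph))
  x * rms / sqrt(mean(x^2))
}

# two-link inverse kinematics: elbow position given shoulder, hand target
solve_elbow <- function(shoulder, hand, bend_ref) {
  L1 <- ARM_SEGMENTS[["upper"]]
  L2 <- ARM_SEGMENTS[["forearm"]] + ARM_SEGMENTS[["hand"]]
  v <- hand - shoulder
  r <- sqrt(sum(v^2))
  u <- v / r
  cosb <- (L1^2 + r^2 - L2^2) / (2 * L1 * r)
  cosb <- pmin(1, pmax(-1, cosb))
  w <- bend_ref - sum(bend_ref * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) w <- c(0, 0, 1) - u[3L] * u else w <- w / nw
  shoulder + L1 * (cosb * u + sqrt(1 - cosb^2) * w)
}

#' Generate one synthetic item recording
#'
#' Drives the hand along the item's characteristic path with a minimum-jerk
#' velocity profile scaled by the score-dependent amplitude fraction, places
#' elbow and wrist by fixed-segment two-link arm kinematics, holds the trunk
#' joints still, superimposes band-limited tremor on the arm (full amplitude
#' at the hand, attenuated up the chain) and white sensor jitter on every
#' joint, and wraps still padding around the reach. Fully reproducible from
#' the seed.
#'
#' @param params A [motion_params()].
#' @param seed Integer seed.
#' @return A [motion_recording()] at `params$frame_rate`.
#' @export
synth_motion <- function(params, seed = 1L) {
  stopifnot(inherits(params, "motion_params"))
  with_seed(seed, synth_motion_impl(params))
}

synth_motion_impl <- function(p) {
  fs <- p$frame_rate
  amp_frac <- p$amplitude_fraction %||% switch(as.character(p$score_class),
    "0" = stats::runif(1, 0.00, 0.20),
    "1" = stats::runif(1, 0.30, 0.70),
    "2" = stats::runif(1, 0.80, 1.00))
  spec <- item_motion_table()[p$item, ]
  dir <- spec[c("dx", "dy", "dz")]
  dir <- dir / sqrt(sum(dir^2))
  A <- amp_frac * spec[["range"]]

  # static trunk landmarks (camera frame: x lateral, y up, z depth)
  sc <- c(0, 0.55, 2.30)
  head <- sc + c(0, 0.22, 0)
  sh_L <- sc + c(ARM_SEGMENTS[["half_shoulder"]], -0.02, 0)
  sh_R <- sc + c(-ARM_SEGMENTS[["half_shoulder"]], -0.02, 0)
  # resting arm: upper arm hanging, forearm forward as if resting on a lap
  elbow0 <- sh_L + ARM_SEGMENTS[["upper"]] * c(0.101, -0.909, 0.404)
  hand0 <- elbow0 + (ARM_SEGMENTS[["forearm"]] + ARM_SEGMENTS[["hand"]]) *
    c(0.102, 0.205, 0.973)

  n_pad <- round(p$pad * fs)
  prof <- min_jerk_trajectory(1, p$duration, fs)$x
  s <- c(rep(0, n_pad), prof, rep(1, n_pad))
  n <- length(s)
  t <- (seq_len(n) - 1L) / fs

  rmax <- 0.97 * (ARM_SEGMENTS[["upper"]] + ARM_SEGMENTS[["forearm"]] +
                    ARM_SEGMENTS[["hand"]])
  bend_ref <- c(0.3, -1, 0.1)
  hand <- matrix(0, n, 3L)
  elbow <- matrix(0, n, 3L)
  wrist <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    h <- hand0 + A * s[i] * dir
    v <- h - sh_L
    r <- sqrt(sum(v^2))
    if (r > rmax) h <- sh_L + v * rmax / r
    e <- solve_elbow(sh_L, h, bend_ref)
    u2 <- (h - e) / sqrt(sum((h - e)^2))
    hand[i, ] <- h
    elbow[i, ] <- e
    wrist[i, ] <- e + ARM_SEGMENTS[["forearm"]] * u2
  }
  # tremor: full at hand, attenuated at wrist and elbow, per axis
  for (ax in 1:3) {
    tr <- tremor_series(n, fs, p$tremor_band, p$tremor_amplitude)
    hand[, ax] <- hand[, ax] + tr
    wrist[, ax] <- wrist[, ax] + 0.7 * tr
    elbow[, ax] <- elbow[, ax] + 0.4 * tr
  }
  frames <- data.frame(t = t)
  static <- list(head = head, shoulder_center = sc,
                 shoulder_L = sh_L, shoulder_R = sh_R,
                 elbow_R = sh_R + ARM_SEGMENTS[["upper"]] * c(-0.101, -0.909, 0.404))
  static$wrist_R <- static$elbow_R + ARM_SEGMENTS[["forearm"]] * c(-0.102, 0.205, 0.973)
  static$hand_R <- static$elbow_R + (ARM_SEGMENTS[["forearm"]] + ARM_SEGMENTS[["hand"]]) *
    c(-0.102, 0.205, 0.973)
  moving <- list(elbow_L = elbow, wrist_L = wrist, hand_L = hand)
  for (j in fma_joints()) {
    m <- if (j %in% names(moving)) moving[[j]]
         else matrix(static[[j]], n, 3L, byrow = TRUE)
    m <- m + matrix(stats::rnorm(3L * n, 0, p$sensor_noise_sd), n, 3L)
    frames[joint_cols(j)] <- m
  }
  rec <- motion_recording(frames, p$subject_id, "left", p$item,
                          frame_rate = fs)
  if (p$side == "right") {
    rec$side <- "right"  # reflect the left-arm build onto the right side
    rec <- mirror_to_left(rec)
    rec$side <- "right"
  }
  rec
}

#' Default stage-to-tremor severity map
#'
#' Hemiplegic-arm tremor RMS amplitude (meters) by Brunnstrom arm stage:
#' larger at low stages, approaching the healthy floor at stage 6. See
#' [motion_params()] for why the scale is micrometers.
#'
#' @return Named numeric vector over stages "1".."6".
#' @export
default_stage_tremor <- function() {
  c("1" = 2.0e-4, "2" = 1.4e-4, "3" = 1.0e-4,
    "4" = 6.0e-5, "5" = 3.5e-5, "6" = 2.0e-5)
}

#' Generate a synthetic cohort of recordings and score table
#'
#' Emulates the study design the pipeline expects: each synthetic subject has
#' a hemiplegic arm with severity-dependent item scores and stage-dependent
#' tremor, and a non-hemiplegic arm performing at full amplitude with
#' near-floor tremor. For every item, exactly `n_per_class` subjects receive
#' each score class (assignment follows a subject-level severity draw, so
#' item scores, Brunnstrom stage and tremor are mutually consistent).
#' Hemiplegic-arm recordings are generated for every item in `items`; both
#' arms additionally record the flexor-synergy elbow-flexion motion used for
#' the smoothness analysis.
#'
#' @param n_per_class Subjects per score class; the cohort has
#'   `3 * n_per_class` subjects.
#' @param items Items to record (default all 13).
#' @param stage_tremor Stage-to-tremor map, see [default_stage_tremor()].
#' @param seed Integer seed.
#' @param frame_rate Sampling rate in Hz (default 30).
#' @return List: `$recordings` (named list of [motion_recording()]),
#'   `$index` (data.frame: recording name, subject, role, side, item,
#'   generative score), `$cohort` (a [cohort_table()] of generative labels).
#' @export
synth_cohort <- function(n_per_class, items = fma_items(),
                         stage_tremor = default_stage_tremor(), seed = 1L,
                         frame_rate = 30) {
  stopifnot(n_per_class >= 1L)
  items <- vapply(items, match_item, character(1), USE.NAMES = FALSE)
  n <- 3L * as.integer(n_per_class)
  jerk_item <- "elbow_flexion"

  plan <- with_seed(seed, {
    severity <- stats::runif(n)  # 0 = intact, 1 = most impaired
    stage <- pmax(1L, pmin(6L, as.integer(ceiling((1 - severity) * 6))))
    hemi_side <- sample(c("left", "right"), n, replace = TRUE)
    # per item: most severe third scores 0, middle 1, least severe 2,
    # with per-item noise so items disagree realistically
    scores <- sapply(items, function(it) {
      noisy <- severity + stats::rnorm(n, 0, 0.12)
      cls <- integer(n)
      ord <- order(noisy, decreasing = TRUE)
      cls[ord[seq_len(n_per_class)]] <- 0L
      cls[ord[n_per_class + seq_len(n_per_class)]] <- 1L
      cls[ord[2L * n_per_class + seq_len(n_per_class)]] <- 2L
      cls
    })
    colnames(scores) <- items
    extra_items <- round(40 * (1 - severity) * stats::runif(n, 0.8, 1.0))
    list(severity = severity, stage = stage, hemi_side = hemi_side,
         scores = scores, extra = extra_items)
  })

  subj <- sprintf("S%03d", seq_len(n))
  recordings <- list()
  index <- list()
  add_rec <- function(rec, subject, role, item, score) {
    nm <- paste(subject, role, item, sep = "_")
    recordings[[nm]] <<- rec
    index[[length(index) + 1L]] <<- data.frame(
      name = nm, subject_id = subject, role = role, side = rec$side,
      item = item, score = score)
  }
  for (i in seq_len(n)) {
    tremor <- unname(stage_tremor[as.character(plan$stage[i])])
    for (it in items) {
      sc <- plan$scores[i, it]
      p <- motion_params(it, sc, tremor_amplitude = tremor,
                         side = plan$hemi_side[i], subject_id = subj[i],
                         frame_rate = frame_rate)
      add_rec(synth_motion(p, seed = seed + 7919L * i + 131L * match(it, items)),
              subj[i], "hemiplegic", it, sc)
    }
    other <- if (plan$hemi_side[i] == "left") "right" else "left"
    p_nh <- motion_params(jerk_item, 2L, tremor_amplitude = 2e-5,
                          side = other, subject_id = subj[i],
                          frame_rate = frame_rate)
    add_rec(synth_motion(p_nh, seed = seed + 7919L * i + 104729L),
            subj[i], "nonhemiplegic", jerk_item, 2L)
  }
  full_scores <- matrix(2L, n, 13L, dimnames = list(NULL, fma_items()))
  full_scores[, items] <- plan$scores
  sum13 <- rowSums(full_scores)
  df <- data.frame(subject_id = subj, hemiplegic_side = plan$hemi_side,
                   brunnstrom_stage = plan$stage)
  for (it in fma_items()) df[[paste0("score_", it)]] <- full_scores[, it]
  df$sum_13 <- sum13
  df$total_33 <- pmin(FMA_UE_TOTAL_MAX, sum13 + plan$extra)
  list(recordings = recordings, index = do.call(rbind, index),
       cohort = cohort_table(df))
}
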