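# Synthetic two-channel ground contact force generator with ground-truth
# labels. Each gait cycle is a pair of overlapping raised-cosine humps:
# the heel loads over the first ~75% of stance, the ball over the last
# ~75%, so mid-stance carries both and the hand-off reproduces the
# heel-strike -> stance -> heel-off -> swing progression.

# evaluate an expression under a temporary RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Parameters of the synthetic gait force generator
#'
#' Defaults describe an average adult (67.3 kg) walking on a treadmill at
#' 4 km/h. The peak force law is linear in speed,
#' `peak = mass_kg * 9.81 * peak_scale * (0.4 + 0.1 * (speed_kmh - 2))`,
#' so that feet strike harder at higher speed; with the default
#' `peak_scale` the per-cycle maxima stay within 300--1300 N over the
#' 2--6 km/h treadmill range and the per-cycle minima within 0--5 N, the
#' ranges observed for level walking.
#'
#' @param speed_kmh Walking speed in km/h (default 4).
#' @param cadence_hz Gait cycles per second for one foot (default 0.9,
#'   i.e. a 1.11 s stride).
#' @param stance_fraction Fraction of the cycle spent in stance (default
#'   0.6).
#' @param mass_kg Body mass in kilograms (default 67.3).
#' @param peak_scale Dimensionless gain of the speed-to-peak law (default
#'   1.5).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise in
#'   newtons (default 2; small against the 15 N initial low threshold).
#' @param baseline Resting force offset in newtons (default 0).
#' @param seed Optional integer seed; when given, generation is
#'   reproducible and leaves the global RNG state untouched.
#' @return An object of class `gait_profile_params`.
#' @examples
#' gait_profile_params(speed_kmh = 5, seed = 1)
#' @export
gait_profile_params <- function(speed_kmh = 4, cadence_hz = 0.9,
                                stance_fraction = 0.6, mass_kg = 67.3,
                                peak_scale = 1.5, noise_sd = 2,
                                baseline = 0, seed = NULL) {
  if (!(speed_kmh > 0)) stop("`speed_kmh` must be positive", call. = FALSE)
  if (!(cadence_hz > 0)) stop("`cadence_hz` must be positive", call. = FALSE)
  if (!(stance_fraction > 0 && stance_fraction < 1)) {
    stop("`stance_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (!(mass_kg > 0)) stop("`mass_kg` must be positive", call. = FALSE)
  if (!(peak_scale > 0)) stop("`peak_scale` must be positive", call. = FALSE)
  if (!(noise_sd >= 0)) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (!(baseline >= 0)) stop("`baseline` must be nonnegative", call. = FALSE)
  structure(
    list(speed_kmh = speed_kmh, cadence_hz = cadence_hz,
         stance_fraction = stance_fraction, mass_kg = mass_kg,
         peak_scale = peak_scale, noise_sd = noise_sd,
         baseline = baseline, seed = seed),
    class = "gait_profile_params"
  )
}

#' @export
print.gait_profile_params <- function(x, ...) {
  cat(sprintf(
    "<gait_profile_params> %g km/h, cadence %g Hz, stance %.0f%%, mass %g kg, peak %.1f N, noise sd %g N\n",
    x$speed_kmh, x$cadence_hz, 100 * x$stance_fraction, x$mass_kg,
    peak_force(x$speed_kmh, x), x$noise_sd
  ))
  invisible(x)
}

#' Peak ground contact force for a walking speed
#'
#' The generator's linear speed-to-peak law (see [gait_profile_params()]).
#'
#' @param speed_kmh Walking speed in km/h.
#' @param params A [gait_profile_params()] supplying mass and gain.
#' @return Peak force in newtons, strictly increasing in `speed_kmh`.
#' @export
peak_force <- function(speed_kmh, params = gait_profile_params()) {
  params$mass_kg * 9.81 * params$peak_scale * (0.4 + 0.1 * (speed_kmh - 2))
}

# raised-cosine (Hann) hump on [0, 1], zero outside
.hump <- function(x) {
  ifelse(x >= 0 & x <= 1, 0.5 * (1 - cos(2 * pi * x)), 0)
}

# Core synthesis from a per-cycle peak amplitude vector. Ground truth
# transitions are placed at the half-peak crossings of the noise-free
# humps, so truth is exactly the Table-of-rules labelling of the clean
# waveform thresholded at 50% of each cycle's peak.
.synth_gcf <- function(amps, params, n, fs) {
  t <- (seq_len(n) - 1) / fs
  cyc <- pmin(floor(t * params$cadence_hz), length(amps) - 1L)
  u <- t * params$cadence_hz - cyc          # phase within cycle, [0, 1)
  A <- amps[cyc + 1L]
  S <- params$stance_fraction
  W <- 0.75 * S                             # each hump spans 75% of stance
  heel_hump <- A * .hump(u / W)
  ball_hump <- A * .hump((u - 0.25 * S) / W)

  heel_on <- ifelse(heel_hump >= 0.5 * A, "on_ground", "off_ground")
  ball_on <- ifelse(ball_hump >= 0.5 * A, "on_ground", "off_ground")
  truth <- label_sample(heel_on, ball_on)

  noisy <- function(clean) {
    x <- clean + params$baseline
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(n, sd = params$noise_sd)
    }
    pmax(x, 0)
  }
  f_ball <- noisy(ball_hump)
  f_heel <- noisy(heel_hump)

  list(
    ball = gcf_recording(t, f_ball, "ball", fs = fs),
    heel = gcf_recording(t, f_heel, "heel", fs = fs),
    truth = truth,
    truth_events = detect_sequence(heel_on, ball_on, time_s = t)$events
  )
}

#' Generate a constant-speed synthetic walk
#'
#' @param params A [gait_profile_params()].
#' @param duration_s Trial duration in seconds (default 30).
#' @param fs Sampling rate in Hz (default 2000), giving
#'   `duration_s * fs` samples per channel.
#' @return A list of class `synthetic_walk` with elements `ball` and `heel`
#'   ([gcf_recording()]s), `truth` (per-sample ground-truth gait labels),
#'   `truth_events` (data frame of ground-truth event times),
#'   `n_cycles` (number of complete gait cycles in the trial) and `params`.
#' @examples
#' w <- generate_walk(gait_profile_params(seed = 1), duration_s = 5, fs = 200)
#' length(w$ball$f)
#' @export
generate_walk <- function(params = gait_profile_params(), duration_s = 30,
                          fs = 2000) {
  stopifnot(inherits(params, "gait_profile_params"))
  if (!(duration_s > 0)) stop("`duration_s` must be positive", call. = FALSE)
  if (!(fs > 0)) stop("`fs` must be positive", call. = FALSE)
  n <- round(duration_s * fs)
  n_cycles_total <- ceiling(duration_s * params$cadence_hz) + 1L
  amps <- rep(peak_force(params$speed_kmh, params), n_cycles_total)
  out <- .with_seed(params$seed, .synth_gcf(amps, params, n, fs))
  out$n_cycles <- floor(duration_s * params$cadence_hz)
  out$params <- params
  class(out) <- "synthetic_walk"
  out
}

#' Generate a walk whose speed changes between segments
#'
#' Concatenates constant-speed segments; the peak amplitude switches at the
#' first cycle start at or after each segment boundary, so every cycle is
#' internally consistent (no mid-cycle discontinuity).
#'
#' @param params A [gait_profile_params()]; its `speed_kmh` is overridden
#'   per segment.
#' @param speeds A data frame (or 2-column matrix) with columns `speed_kmh`
#'   and `duration_s`, one row per segment, in order.
#' @param fs Sampling rate in Hz.
#' @return Same structure as [generate_walk()], plus a `segments` data
#'   frame with each segment's speed, start time and peak force.
#' @examples
#' sp <- data.frame(speed_kmh = c(2, 6), duration_s = c(5, 5))
#' w <- generate_speed_change(gait_profile_params(seed = 1), sp, fs = 200)
#' @export
generate_speed_change <- function(params = gait_profile_params(), speeds,
                                  fs = 2000) {
  stopifnot(inherits(params, "gait_profile_params"))
  speeds <- as.data.frame(speeds)
  if (nrow(speeds) == 0L) stop("`speeds` must be non-empty", call. = FALSE)
  if (!all(c("speed_kmh", "duration_s") %in% names(speeds))) {
    stop("`speeds` needs columns `speed_kmh` and `duration_s`",
         call. = FALSE)
  }
  if (any(speeds$duration_s <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  duration_s <- sum(speeds$duration_s)
  n <- round(duration_s * fs)
  n_cycles_total <- ceiling(duration_s * params$cadence_hz) + 1L
  seg_start <- cumsum(c(0, speeds$duration_s))[seq_len(nrow(speeds))]
  cycle_start_t <- (seq_len(n_cycles_total) - 1L) / params$cadence_hz
  seg_of_cycle <- findInterval(cycle_start_t, seg_start)
  amps <- peak_force(speeds$speed_kmh[seg_of_cycle], params)
  out <- .with_seed(params$seed, .synth_gcf(amps, params, n, fs))
  out$n_cycles <- floor(duration_s * params$cadence_hz)
  out$params <- params
  out$segments <- data.frame(
    speed_kmh = speeds$speed_kmh,
    start_s = seg_start,
    duration_s = speeds$duration_s,
    peak_N = peak_force(speeds$speed_kmh, params)
  )
  class(out) <- "synthetic_walk"
  out
}

#' @export
print.synthetic_walk <- function(x, ...) {
  cat(sprintf(
    "<synthetic_walk> %d samples/channel at %g Hz, %d complete cycles, peak %.1f N\n",
    length(x$ball$f), x$ball$fs, x$n_cycles, max(x$heel$f)
  ))
  invisible(x)
}

#' Write a synthetic walk to the shared CSV schemas
#'
#' @param walk A `synthetic_walk` from [generate_walk()] or
#'   [generate_speed_change()].
#' @param path Output path for the force CSV (`time_s,ball_N,heel_N`).
#' @param truth_path Optional path for the truth CSV (`time_s,truth_label`).
#' @return `path`, invisibly.
#' @export
write_walk_csv <- function(walk, path, truth_path = NULL) {
  stopifnot(inherits(walk, "synthetic_walk"))
  write_gcf_csv(walk$ball, walk$heel, path)
  if (!is.null(truth_path)) {
    d <- data.frame(
      time_s = sprintf("%.6f", walk$ball$t),
      truth_label = walk$truth
    )
    utils::write.csv(d, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
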