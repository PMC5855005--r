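test_that("a 30 s trial at 2000 Hz yields exactly 60000 samples per channel", {
  w <- generate_walk(gait_profile_params(seed = 1), duration_s = 30,
                     fs = 2000)
  expect_equal(length(w$ball$f), 60000L)
  expect_equal(length(w$heel$f), 60000L)
  expect_equal(length(w$truth), 60000L)
  expect_equal(w$ball$fs, 2000)
})

test_that("noise-free generation is deterministic with identical cycle peaks", {
  p <- gait_profile_params(noise_sd = 0)
  w <- generate_walk(p, duration_s = 10, fs = 250)
  ext <- find_cycle_extrema(w$heel, split_level = tam_threshold(w$heel))
  # cycle peaks identical up to the sub-sample phase of the hump centre
  expect_lt(diff(range(ext$local_maxima)), 1e-3 * peak_force(4, p))
  expect_equal(max(w$heel$f), peak_force(4, p), tolerance = 1e-5)
  expect_equal(min(w$heel$f), 0)  # baseline exactly
  w2 <- generate_walk(p, duration_s = 10, fs = 250)
  expect_identical(w$heel$f, w2$heel$f)
})

test_that("the seed contract gives bitwise reproducibility and fresh noise", {
  p1 <- gait_profile_params(seed = 11)
  wa <- generate_walk(p1, duration_s = 2, fs = 200)
  wb <- generate_walk(p1, duration_s = 2, fs = 200)
  expect_identical(wa$ball$f, wb$ball$f)
  expect_identical(wa$heel$f, wb$heel$f)
  wc <- generate_walk(gait_profile_params(seed = 12), duration_s = 2,
                      fs = 200)
  expect_false(identical(wa$ball$f, wc$ball$f))
  # seeded generation leaves the global RNG stream untouched
  set.seed(77)
  before <- stats::runif(1)
  set.seed(77)
  invisible(generate_walk(p1, duration_s = 1, fs = 100))
  expect_identical(stats::runif(1), before)
})

test_that("peak force increases strictly with walking speed", {
  p <- gait_profile_params()
  peaks <- peak_force(c(2, 3, 4, 5, 6), p)
  expect_true(all(diff(peaks) > 0))
})

test_that("default per-cycle extrema stay inside the walking-force envelope", {
  for (speed in c(2, 3, 4, 5, 6)) {
    p <- gait_profile_params(speed_kmh = speed, seed = speed)
    w <- generate_walk(p, duration_s = 8, fs = 250)
    ext <- find_cycle_extrema(w$heel, split_level = tam_threshold(w$heel))
    expect_true(all(ext$local_maxima >= 300 & ext$local_maxima <= 1300))
    expect_true(all(ext$local_minima >= 0 & ext$local_minima <= 5))
  }
})

test_that("half-peak thresholding of the clean waveform reproduces the truth labels", {
  w <- small_walk(duration_s = 6, fs = 250, noise_sd = 0)
  A <- peak_force(4, w$params)
  heel_status <- classify_with_threshold(w$heel, 0.5 * A)
  ball_status <- classify_with_threshold(w$ball, 0.5 * A)
  relabel <- label_sample(heel_status, ball_status)
  # transitions may shift by a couple of samples at the crossings
  expect_gt(mean(relabel == w$truth), 1 - 8 * 2 / length(relabel))
})

test_that("speed switching is cycle-aligned with strictly increasing peaks", {
  p <- gait_profile_params(noise_sd = 0)
  sp <- data.frame(speed_kmh = c(2, 6), duration_s = c(5, 5))
  w <- generate_speed_change(p, sp, fs = 250)
  ext <- find_cycle_extrema(w$heel, split_level = 50)
  # two amplitude levels, each within sampling tolerance of its peak law,
  # and all low-speed cycles precede all high-speed cycles
  hi <- ext$local_maxima > 600
  expect_false(is.unsorted(hi))
  expect_equal(mean(ext$local_maxima[!hi]), peak_force(2, p),
               tolerance = 1e-3)
  expect_equal(mean(ext$local_maxima[hi]), peak_force(6, p),
               tolerance = 1e-3)
  # single segment degenerates to the constant-speed generator
  p1 <- gait_profile_params(seed = 4)
  one <- generate_speed_change(p1, data.frame(speed_kmh = 4,
                                              duration_s = 4), fs = 200)
  ref <- generate_walk(p1, duration_s = 4, fs = 200)
  expect_identical(one$heel$f, ref$heel$f)
  expect_identical(one$ball$f, ref$ball$f)
  expect_error(generate_speed_change(p, data.frame()), "non-empty")
})

test_that("online thresholds adapt after a speed switch at the contraction rate", {
  p <- gait_profile_params(noise_sd = 0, cadence_hz = 0.9)
  sp <- data.frame(speed_kmh = c(2, 6), duration_s = c(10, 10))
  w <- generate_speed_change(p, sp, fs = 250)
  frec <- lowpass_filter(w$heel)
  res <- run_sttta(frec, sttta_params())
  ev <- res$events[res$events$threshold == "t_h", ]
  # stationary target from the filtered trace's own post-switch extrema
  # (the causal filter slightly undershoots below zero between humps)
  post_f <- frec$f[frec$t > 12]
  fp_new <- fixed_point_thresholds(max(post_f), min(post_f),
                                   sttta_params())
  p0 <- sttta_params()
  r <- (1 - p0$lam) * (1 - p0$gamma)
  post <- ev[ev$time_s > 10, ]
  errs <- abs(post$new_N - fp_new$t_h)
  # errors contract geometrically at (1-lam)(1-gamma) per cycle ...
  expect_true(all(diff(errs[1:6]) < 0))
  ratios <- errs[3:6] / errs[2:5]
  expect_true(all(abs(ratios - r) < 0.08))
  # ... reaching the 1%-of-t_h band about six cycles after the switch
  expect_lt(errs[6], 0.01 * fp_new$t_h)
})
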