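test_that("initial state carries the initial thresholds and zeroed counters", {
  st <- init_state(sttta_params())
  expect_equal(c(st$t_l, st$t_m, st$t_h), c(15, 20, 25))
  expect_equal(st$i, 0L)
  expect_equal(st$j, 0L)
  expect_identical(st$phase_point, "UNSYNCED")
  expect_true(is.na(st$max_acc) && is.na(st$min_acc))
  expect_error(sttta_params(t_l0 = 20, t_m0 = 20), "t_l0 < t_m0 < t_h0")
  expect_error(sttta_params(beta = 0.03, gamma = 0.05), "gamma < beta")
})

test_that("contact status splits at the high threshold with on-ground boundary", {
  expect_equal(classify_sample(30, 25), "on_ground")
  expect_equal(classify_sample(25, 25), "on_ground")
  expect_equal(classify_sample(24.999, 25), "off_ground")
  expect_error(classify_sample(Inf, 25), "finite")
})

test_that("first square-wave cycle reproduces the hand-applied update rules", {
  # 500 N for 0.6 s / 0 N for 0.4 s at fs = 1000; T_max = 500, T_min = 0
  f <- square_wave(500, on_samples = 600, off_samples = 400, n_cycles = 2)
  res <- run_sttta(f, sttta_params())
  ev <- res$events
  # t_h and t_m recomputed from the first cycle's maximum and prior t_l = 15
  expect_equal(ev$new_N[ev$threshold == "t_h"][1], 0.071 * (500 - 15) + 15)
  expect_equal(ev$new_N[ev$threshold == "t_m"][1], 0.042 * (500 - 15) + 15)
  # t_l recomputed at the next rise from T_min = 0 and the new t_m
  expect_equal(ev$new_N[ev$threshold == "t_l"][1], 0.5 * 0 + 0.5 * 35.37)
  # update order within the cycle: t_h, then t_m, then t_l
  expect_equal(ev$threshold[1:3], c("t_h", "t_m", "t_l"))
})

test_that("sub-threshold input never fires a cycle event", {
  res <- run_sttta(rep(10, 500), sttta_params())
  expect_equal(nrow(res$events), 0L)
  expect_true(all(res$status == "off_ground"))
  expect_equal(res$state$i, 0L)
  expect_equal(unique(res$thresholds$t_h), 25)
})

test_that("fixed-point triple solves the stationary update equations", {
  p <- sttta_params()
  fp <- fixed_point_thresholds(1000, 0, p)
  expect_equal(fp$t_l, 40.307, tolerance = 1e-4)
  expect_equal(fp$t_m, 80.614, tolerance = 1e-4)
  expect_equal(fp$t_h, 108.445, tolerance = 1e-4)
  expect_equal(fp$t_m, 42 / 0.521, tolerance = 1e-9)
  # the triple is invariant under one more round of updates
  t_m2 <- p$gamma * (1000 - fp$t_l) + fp$t_l
  t_h2 <- p$beta * (1000 - fp$t_l) + fp$t_l
  t_l2 <- p$lam * 0 + (1 - p$lam) * t_m2
  expect_equal(c(t_l2, t_m2, t_h2), c(fp$t_l, fp$t_m, fp$t_h))
  # lam -> 1 collapses the low threshold onto the cycle minimum
  p1 <- sttta_params(lam = 1 - 1e-12)
  expect_equal(fixed_point_thresholds(800, 3, p1)$t_l, 3, tolerance = 1e-6)
  expect_error(fixed_point_thresholds(5, 5, p), "m < M")
  # ordering holds arbitrarily close to degeneracy
  fp2 <- fixed_point_thresholds(10 + 1e-6, 10, p)
  expect_true(fp2$t_l < fp2$t_m && fp2$t_m < fp2$t_h)
})

test_that("thresholds converge geometrically to the fixed point on periodic input", {
  p <- sttta_params()
  fp <- fixed_point_thresholds(1000, 0, p)
  f <- square_wave(1000, on_samples = 120, off_samples = 80, n_cycles = 30)
  res <- run_sttta(f, p)
  # contraction ratio (1-lam)(1-gamma) = 0.479: 1e-6 N is reached by cycle 25
  expect_triple_equal(res$state, fp, tol = 1e-6)
  # successive t_l errors shrink by the contraction ratio
  tl_ev <- res$events$new_N[res$events$threshold == "t_l"]
  err <- abs(tl_ev - fp$t_l)
  ratios <- err[-1] / err[-length(err)]
  expect_equal(ratios[1:10], rep((1 - p$lam) * (1 - p$gamma), 10),
               tolerance = 1e-6)
})

test_that("step-by-step folding equals the batch run exactly", {
  w <- small_walk(duration_s = 8, fs = 250, noise_sd = 2, seed = 7)
  rec <- lowpass_filter(w$heel)
  batch <- run_sttta(rec, sttta_params())
  st <- init_state(sttta_params())
  statuses <- character(length(rec))
  for (k in seq_along(rec$f)) {
    out <- step(st, rec$f[k])
    st <- out$state
    statuses[k] <- out$status
  }
  expect_identical(statuses, batch$status)
  expect_equal(st$t_l, batch$state$t_l)
  expect_equal(st$t_m, batch$state$t_m)
  expect_equal(st$t_h, batch$state$t_h)
  expect_identical(st$i, batch$state$i)
  expect_identical(st$j, batch$state$j)
})

test_that("status at a sample is unchanged by altering future samples", {
  w <- small_walk(duration_s = 6, fs = 250, noise_sd = 2, seed = 11)
  f1 <- lowpass_filter(w$ball)$f
  f2 <- f1
  cut <- length(f1) - 200
  f2[(cut + 1):length(f2)] <- 0
  r1 <- run_sttta(f1, sttta_params())
  r2 <- run_sttta(f2, sttta_params())
  expect_identical(r1$status[1:cut], r2$status[1:cut])
  expect_identical(r1$thresholds$t_h[1:cut], r2$thresholds$t_h[1:cut])
})

test_that("threshold ordering survives every sample and every update", {
  for (seed in 1:5) {
    w <- small_walk(speed_kmh = 2 + seed %% 5, duration_s = 8, fs = 250,
                    noise_sd = 5, seed = seed)
    rec <- lowpass_filter(w$heel)
    res <- run_sttta(rec, sttta_params())
    thr <- res$thresholds
    expect_true(all(thr$t_l < thr$t_m & thr$t_m < thr$t_h))
  }
})

test_that("each threshold updates exactly once per complete cycle", {
  # trial ends just after the rise of cycle N+1 so the final low-threshold
  # update (fired at that rise) falls inside the trace
  n_cyc <- 12
  cad <- 0.9
  w <- generate_walk(
    gait_profile_params(cadence_hz = cad, noise_sd = 2, seed = 3),
    duration_s = (n_cyc + 0.3) / cad, fs = 400
  )
  res <- run_sttta(lowpass_filter(w$heel), sttta_params())
  counts <- table(res$events$threshold)
  expect_equal(unname(counts[c("t_h", "t_m", "t_l")]),
               rep(n_cyc, 3), ignore_attr = TRUE)
  expect_equal(res$state$i, n_cyc)
})

test_that("a pathological update is rejected with a warning, keeping prior values", {
  # low beta/gamma almost equal and a tiny maximum drive t_h toward t_m
  p <- sttta_params(beta = 0.0501, gamma = 0.05, t_l0 = 15, t_m0 = 20,
                    t_h0 = 25)
  # cycle 1: max 500 -> t_h ~ 39.3, t_m ~ 39.25, nearly collapsed;
  # cycle 2 with max barely above t_h makes the recomputed t_h fall below t_m
  f <- c(square_wave(500, on_samples = 100, off_samples = 80, n_cycles = 1),
         square_wave(45, on_samples = 100, off_samples = 80, n_cycles = 1),
         rep(0, 10))
  expect_warning(res <- run_sttta(f, p), "rejected")
  thr <- res$thresholds
  expect_true(all(thr$t_l < thr$t_m & thr$t_m < thr$t_h))
})

test_that("cycle counters i and j may legitimately differ", {
  # one full cycle, then a hump that rises above t_h but never falls below
  # t_l (incomplete cycle): j advances at the maximum, i does not
  f <- c(square_wave(500, on_samples = 100, off_samples = 80, n_cycles = 1),
         rep(0, 50), rep(500, 100), rep(30, 200))
  res <- run_sttta(f, sttta_params())
  expect_gt(res$state$j, res$state$i)
})
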