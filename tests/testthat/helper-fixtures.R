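# Shared fixtures, generated in code at test time.

# square wave alternating `hi` N for on_samples and `lo` N for off_samples,
# repeated n_cycles times (starts low so the first rise is a clean onset)
square_wave <- function(hi, lo = 0, on_samples = 600, off_samples = 400,
                        n_cycles = 5) {
  rep(rep(c(lo, hi), n_cycles),
      times = rep(c(off_samples, on_samples), n_cycles))
}

# small, quick synthetic walk: coarse sampling keeps unit tests fast
small_walk <- function(speed_kmh = 4, duration_s = 10, fs = 250,
                       noise_sd = 0, seed = 42, cadence_hz = 0.9) {
  generate_walk(
    gait_profile_params(speed_kmh = speed_kmh, cadence_hz = cadence_hz,
                        noise_sd = noise_sd, seed = seed),
    duration_s = duration_s, fs = fs
  )
}

# filter both channels of a walk with the standard causal low-pass
filtered_pair <- function(walk, cutoff = 10) {
  list(ball = lowpass_filter(walk$ball, cutoff = cutoff),
       heel = lowpass_filter(walk$heel, cutoff = cutoff))
}

expect_triple_equal <- function(state, triple, tol) {
  expect_lt(abs(state$t_l - triple$t_l), tol)
  expect_lt(abs(state$t_m - triple$t_m), tol)
  expect_lt(abs(state$t_h - triple$t_h), tol)
}
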