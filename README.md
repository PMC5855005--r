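# gaitphase

Real-time gait phase detection from two-channel ground contact forces.

## The problem

Wearable gait analysis commonly instruments a shoe with two force sensitive
resistors (FSRs), one under the ball of the foot and one under the heel.
Thresholding each force stream yields a per-sample *on-ground* /
*off-ground* contact status, and the pair of statuses maps to the gait
phases and events of one foot:

| heel | ball | label |
|------|------|-------------|
| on | on | stance |
| off | off | swing |
| on | off | heel-strike |
| off | on | heel-off |

Fixed thresholds are brittle: peak contact force varies with the wearer's
mass and grows with walking speed, so a threshold tuned for one person at
one speed misfires for another. `gaitphase` implements a **self-tuning
triple-threshold detector**: an online state machine per channel that
tracks each gait cycle's force maximum and minimum and recomputes its three
thresholds once per cycle,

- high: `t_h <- beta * (T_max - t_l) + t_l` (also the contact threshold:
  `F >= t_h` is on-ground),
- middle: `t_m <- gamma * (T_max - t_l) + t_l` (times the updates),
- low: `t_l <- lam * T_min + (1 - lam) * t_m`,

with defaults `beta = 0.071`, `gamma = 0.042`, `lam = 0.5` and initial
thresholds (15, 20, 25) N. The middle threshold exists to schedule the
other two updates so that each fires **exactly once per cycle** even when
the force wobbles around a freshly computed threshold. The package also
provides the three classic fixed-threshold comparators (5% body weight;
10% of the global force span; averaged per-cycle extrema with
`alpha = 0.084`), the phase/event rule table above, per-sample reliability
scoring with a `(beta, gamma)` grid search, a 10 Hz Butterworth
conditioning filter (causal or zero-phase), CSV input/output for force and
label traces, and a seeded synthetic gait generator so the whole pipeline
is testable without recorded data.

## Worked example

```r
library(gaitphase)

walk <- generate_walk(gait_profile_params(seed = 1))   # 30 s at 2000 Hz
ball <- lowpass_filter(walk$ball)
heel <- lowpass_filter(walk$heel)

run_sttta(heel, sttta_params())
#> <sttta_result> 60000 samples, 80 threshold updates, 26 completed cycles,
#>   final (t_l, t_m, t_h) = (22.317, 46.331, 62.912) N

fixed_point_thresholds(1000, 0, sttta_params())
#> <threshold_triple> (t_l, t_m, t_h) = (40.307, 80.614, 108.445) N

compare_methods(ball, heel, "sttta", "tam", burn_in_cycles = 2)
#> <reliability_report> sttta vs tam: 99.20% over 55409 samples
```

The first run shows the detector adapting on a simulated 4 km/h walk: 26
complete cycles, each recomputing the triple once, ending with a high
threshold (62.9 N) sitting about 10% of the way up the ~590 N force humps —
the same placement the post-hoc span method computes, which is why the two
agree on 99.2% of samples once the two-cycle cold-start burn-in is
excluded. `fixed_point_thresholds()` gives the closed-form stationary
triple for constant per-cycle extrema (here 1000/0 N), the analytic target
used by the convergence tests.

A command-line wrapper covers the same pipeline
(`inst/cli/gaitphase simulate | detect | compare | tune`):

```sh
Rscript inst/cli/gaitphase simulate --output walk.csv --seed 1
Rscript inst/cli/gaitphase detect --input walk.csv --method sttta --output labels.csv
Rscript inst/cli/gaitphase compare --input walk.csv --method-a sttta --method-b tam --burn-in 2 --output report.json
```

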