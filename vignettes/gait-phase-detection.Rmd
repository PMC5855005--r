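---
title: "Adaptive triple-threshold gait phase detection from ground contact forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive triple-threshold gait phase detection from ground contact forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem

Two force sensitive resistors (FSRs) under the sole — one at the ball of the
foot, one at the heel — each produce a ground contact force (GCF) stream in
newtons. Thresholding each stream splits it into *on-ground* (sensor pressed)
and *off-ground* samples, and the pair of statuses maps to gait phases and
events:

| heel | ball | label | kind |
|------|------|-------------|-------|
| on | on | stance | phase |
| off | off | swing | phase |
| on | off | heel-strike | event |
| off | on | heel-off | event |

A single fixed threshold has to be re-chosen for every wearer and every
walking speed, because peak GCF grows with both body mass and speed. The
package's core is an online detector whose thresholds re-tune themselves
once per gait cycle, so the same initial setting works for any wearer at any
speed on level ground.

## The self-tuning triple-threshold detector

Each channel runs an independent state machine carrying three ordered
thresholds, low < middle < high ($T_L < T_M < T_H$). Per cycle:

* while the force stays at or above $T_H$, the running **cycle maximum**
  $T_{\max}$ is tracked; $T_H$ is also the *main* threshold that defines the
  contact status ($F \ge T_H$ is on-ground, the boundary inclusive);
* at the downward crossing of $T_M$ the maximum is final and the high
  threshold is recomputed, $T_H \leftarrow \beta\,(T_{\max}-T_L) + T_L$;
* at the downward crossing of $T_L$ the middle threshold follows,
  $T_M \leftarrow \gamma\,(T_{\max}-T_L) + T_L$, and the **cycle minimum**
  $T_{\min}$ search opens while the force stays at or below $T_L$;
* at the next upward crossing of $T_M$ the minimum is final and
  $T_L \leftarrow \lambda\,T_{\min} + (1-\lambda)\,T_M$.

The middle threshold exists purely to time the recomputations: recomputing at
the exit of the $T_H$ region itself can fire twice in one cycle when the
force wobbles around the freshly lowered threshold. Encoding the
within-cycle event order in the state machine makes "at most one update of
each threshold per cycle" structural rather than statistical: once the high
threshold has been recomputed, later excursions above it cannot re-open the
maximum search until the cycle completes. Within an open search region,
re-entries (force dipping below $T_H$ and back, before the $T_M$ crossing)
continue the same extremum accumulation rather than restarting it, which is
what makes the running extrema robust to small dips.

### Parameters

| parameter | default | units | meaning |
|-----------|---------|-------|---------|
| $\beta$ | 0.071 | — | position of $T_H$ between $T_L$ and the cycle maximum |
| $\gamma$ | 0.042 | — | position of $T_M$ likewise; must satisfy $\gamma < \beta$ |
| $\lambda$ | 0.5 | — | weight of the cycle minimum in the $T_L$ update |
| $T_L(1), T_M(1), T_H(1)$ | 15, 20, 25 | N | initial thresholds |

The initial triple only needs to sit strictly between the expected per-cycle
minima (0–5 N for level walking) and maxima (300–1300 N); the defaults are a
deliberately arbitrary choice inside that band, and the same setting is
meant to serve every wearer — adaptability, not per-subject calibration, is
the design goal. $\gamma < \beta$ guarantees the recomputed triple stays
ordered; a recomputation that would violate the ordering (possible only on
pathological input) is rejected with a warning and the previous value kept,
because a live detector should degrade rather than halt.

### Convergence behaviour

With constant per-cycle extrema $M$ and $m$ the three update rules have a
unique fixed point, returned in closed form by `fixed_point_thresholds()`:

```{r}
fixed_point_thresholds(1000, 0, sttta_params())
```

Substituting the $T_M$ rule into the $T_L$ rule shows the low threshold
follows a scalar linear recursion with contraction ratio
$(1-\lambda)(1-\gamma) \approx 0.479$ per cycle: the distance to the fixed
point roughly halves every cycle. Two practical consequences, both visible
in the test suite:

* from the default initial triple, convergence to within $10^{-6}$ N takes
  about 24 cycles (not a handful — the approach is geometric, never exact
  early);
* after a sudden amplitude change (a speed switch), the *high* threshold
  closes about 70% of its gap in the very first cycle, because it depends
  mostly on the new maximum directly; full convergence to within 1% of the
  new $T_H$ takes about five cycles. Detection quality recovers essentially
  immediately — the high threshold only needs to sit between the new minima
  and maxima, which it does from the first post-switch cycle — while the
  exact stationary values settle geometrically.

### Degenerate inputs and numerical choices

* Crossings are detected between consecutive samples with the inclusive
  conventions of the update rules ($F \ge$ enters the high region,
  $F \le$ enters the low region); a sample exactly at $T_H$ is on-ground.
* A trace that never crosses $T_M$ fires no updates and reports off-ground
  throughout (e.g. a disconnected sensor).
* Cold start: until the first upward $T_M$ crossing the machine is
  unsynchronized; the first $T_L$ update is skipped because no cycle minimum
  exists yet.
* The completed-cycle counter `i` and the completed-extremum counter `j`
  may differ: a hump that rises above $T_H$ but never falls below $T_L$
  finalizes a maximum without completing a cycle.

## Reference methods

Three fixed-threshold methods serve as comparators, behind one interface:

* **body-weight fraction**: $T = 0.05\,m g$ — real-time but
  speed-insensitive and needs the wearer's mass;
* **global span**: $T = T_{\min} + 0.10\,(T_{\max}-T_{\min})$ from the whole
  recording's extrema — post-processing only;
* **averaged per-cycle extrema**: $T = \overline{T}_{\min} +
  \alpha\,(\overline{T}_{\max}-\overline{T}_{\min})$ with $\alpha = 0.084$ —
  post-processing only.

The per-cycle extrema for the third method are located by segmenting the
trace into runs above/below a split level (defaulting to the global-span
threshold of the same recording) and taking one extremum per run. This
segmentation is a documented design choice: any method that yields exactly
one maximum and one minimum per complete cycle would do, and leading or
trailing half-cycles naturally make the two counts differ by one.

## Filtering

Force streams are conditioned by a second-order Butterworth low-pass at
10 Hz (the conventional choice for 2000 Hz GCF acquisition). The default is
a **causal** single forward pass, because the detector's real-time contract
requires the output at sample $k$ to depend only on samples up to $k$; a
zero-phase forward–backward mode is provided for offline analysis parity.
Two consequences of the causal choice worth knowing: the filter delays the
signal slightly (immaterial here, both channels shift together), and its
step response undershoots, so a trace that rests at exactly 0 N between
humps filters to small *negative* values. The detector is specified over
raw force comparisons and handles negative minima without special cases;
analyses that compare against the closed-form fixed point should therefore
measure $M$ and $m$ on the *filtered* trace.

## Reliability scoring

Reliability between two methods is defined here as the percentage of
samples on which their gait labels agree, with the full 4×4 confusion
table; it is symmetric, bounded in $[0, 100]$, and 100 exactly for
identical label sequences. (Agreement over events or phase durations would
be alternative definitions; only the per-sample form is implemented.) An
optional burn-in, counted in complete cycles of the reference method,
excludes the cold-start transient during which the adaptive thresholds are
still converging — the reference methods see the whole recording
post hoc, so scoring their first cycles against a detector that starts from
deliberately uninformed thresholds measures initialization, not detection.

`grid_search()` scans $(\beta, \gamma)$ pairs with $\gamma < \beta$,
averaging the reliability over a set of training recordings against one
reference method, with ties broken toward the smallest $\beta$ then
$\gamma$. The default grid steps by 0.02 over 0.02–0.30; that resolution
locates the plateau in minutes on a laptop, and a finer grid (the search
accepts any numeric vectors) refines it when needed — the reliability
surface around the optimum is flat enough that milli-resolution changes the
score only in its second decimal.

## The synthetic generator

`generate_walk()` emulates what matters statistically about treadmill GCF
data: cyclic single-hump forces per channel, heel loading leading ball
loading within stance, peak amplitude increasing with speed, small additive
Gaussian sensor noise, forces clamped at zero. Each channel's hump is a
raised cosine — the heel's spanning the first 75% of stance, the ball's the
last 75%, overlapping mid-stance. The peak law is linear,
$\mathrm{peak} = m g \cdot \mathrm{peak\_scale}\,(0.4 + 0.1\,(v - 2))$ with
$v$ in km/h: only the *monotonicity* of peak force in speed is
physiologically grounded; the slope and gain are fixture choices, set once
so that the default per-cycle maxima stay within the 300–1300 N band (and
minima within 0–5 N) across the 2–6 km/h range. Defaults: 67.3 kg mass
(an average adult), 0.9 Hz cadence per foot, 60% stance fraction, 2 N noise
(small against the 15 N initial low threshold, so cold start is untouched),
30 s trials at 2000 Hz.

Ground-truth labels place each transition at the half-peak crossing of the
noise-free hump, so the truth is exactly the rule-table labelling of the
clean waveform thresholded at 50% of the cycle peak. Speed switches
(`generate_speed_change()`) change amplitude at cycle starts only, avoiding
mid-cycle discontinuities.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: double-bump stance profiles, inter-cycle timing
variability, sensor drift and hysteresis, crosstalk between FSRs,
pathological gaits, stairs or uneven terrain. Test problem sizes (30 s
trials at 2000 Hz; 100-cycle runs for the update-discipline checks; twenty
randomized 60 000-sample trials for the ordering property) were chosen to
exercise every state transition many hundreds of times while keeping the
full suite in the low minutes.

## Worked example

```{r}
walk <- generate_walk(gait_profile_params(seed = 1))
ball <- lowpass_filter(walk$ball)
heel <- lowpass_filter(walk$heel)

res <- run_sttta(heel, sttta_params())
res
tail(res$thresholds, 2)

rel <- compare_methods(ball, heel, "sttta", "tam", burn_in_cycles = 2)
rel
```

The final heel-channel triple sits near the fixed point implied by the
filtered trace's cycle extrema, and the online detector agrees with the
post-hoc global-span reference on over 99% of samples once the two-cycle
burn-in is excluded.

## Known limitations

* Level, rhythmic walking only: the cycle-order state machine assumes the
  b→c→e→f→g event order; shuffling gaits, stair climbing or terrain-induced
  force spikes can produce incomplete cycles (tolerated, counted via
  `i != j`) or rejected updates (logged as warnings), but no rule set for
  abnormal gait is provided.
* Sub-phases of swing are out of scope; the rule table resolves four
  heel/ball status combinations only.
* The per-sample reliability metric weights long phases more than short
  events; event-timing accuracy is visible in the event tables but not
  summarized in one number.
* Unfiltered high-amplitude white noise (several newtons at 2000 Hz) can
  fire spurious crossings; the intended pipeline always low-pass filters
  first, as the acquisition convention prescribes.
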