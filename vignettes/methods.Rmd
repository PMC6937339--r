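---
title: "Methods: standardized-error scoring of selective voluntary motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized-error scoring of selective voluntary motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmcgame)
```

## The measurement model

The assessment records one tri-axial accelerometer per body segment while a
player steers an avatar along a path using a single target joint. Two
assumptions make angles recoverable from accelerometers alone:

1. **Quasi-static regime.** Within the speed range of the game, movement-
   induced accelerations are a few percent of gravity, so each sensor's
   reading approximates the unit gravity vector expressed in the sensor
   frame. The inclination in a declared two-axis sensor plane is then
   `atan2(-a_u, -a_v)`, with 0° when the y-axis is anti-parallel to gravity
   (hanging limb) and ±90° when perpendicular.
2. **Proximal referencing.** Each joint channel is the pointwise difference
   of a distal and a proximal sensor inclination. Any rigid rotation common
   to the pair — trunk lean during hip play, shoulder anteversion during
   elbow play — cancels algebraically, so compensation strategies cannot
   steer the avatar. This cancellation is exact once both traces are on the
   same grid and processed identically, and the test suite holds it to
   1e-9 degrees.

Where gravity is nearly orthogonal to a channel's measurement plane the
angle is ill-conditioned; samples whose in-plane gravity magnitude falls
below `floor_g` (default 0.05 g) are flagged and bridged by linear
interpolation up to 0.5 s. Longer gaps mark the channel missing rather than
failing the session, and the missing-channel policy (below) decides the
consequence.

The channel vocabulary, pairings and per-channel planes live in one
editable, JSON-serializable table (`channel_table()`, shipped in
`inst/extdata/`). The lower-extremity table defines 10 channels (hip
flexion and rotation, knee, ankle per side, lateral and ventral trunk) from
10 sensors; the upper-extremity table defines 12 channels (shoulder
abduction, elbow, forearm pro/supination, wrist, fingers per side, plus
trunk) from 12 sensors. Per-joint conventions are the least certain part of
the design, which is exactly why they are isolated in a table rather than
in code. Which movement direction steers the avatar upward is likewise a
per-channel `sign`: for the upper extremity the defaults (abduction,
flexion, supination, wrist extension up) are a design choice, as the
steering directions are not fixed by the measurement model.

## Signal processing

* **Resampling.** The hardware emits samples at 29 Hz about 70 % of the
  time and 58 Hz otherwise. All processing happens on a uniform 29 Hz grid
  — the dominant native rate — obtained by linear interpolation; choosing
  the lower rate means the 58 Hz stretches are thinned rather than the
  29 Hz stretches imputed. No extrapolation beyond the recorded span.
* **Filtering.** Zero-phase (forward–backward) 2nd-order Butterworth
  low-pass, default cutoff 3 Hz: voluntary joint movement in this task
  lives well below 3 Hz, and zero-phase filtering preserves timing so that
  tracking error is not confounded by filter delay. The trace is extended
  by edge reflection (3 s) before `filtfilt` so start-up transients stay
  out of the analysis window; DC traces pass unchanged to ~1e-9. Both
  cutoff and order are arguments, so a different filter can be swapped in.
* **Differentiation.** Central differences (one-sided at the ends). The
  involuntary-movement metric works on derivatives deliberately: a player
  who cannot assume the prescribed starting posture but holds still scores
  a zero derivative and is not penalized. The truncation error of central
  differences at 29 Hz is about 0.8 % of the derivative amplitude for a
  1 Hz joint oscillation — far below the biological signal of interest.

## Calibration and the game geometry

The target joint's active range is measured from a ≥ 5 s calibration
recording; active rather than passive range decouples motor control from
strength. The measured span is capped (hip 45°, knee 90°, ankle 90°;
shoulder 70°, elbow 110°, forearm 135°, wrist 135°; fingers uncapped since
no cap is defined for them), then 5° are pruned from each end. Three design
points were genuinely open and are resolved as follows:

* the cap is applied **symmetrically about the measured span's midpoint** —
  the least biased truncation absent a stated rule;
* the order is **cap, then prune**, so the pruning margin is always the
  full 5° inside the playable range;
* pruning applies to **both extremities** by default (`prune_deg` is an
  argument), although it is only explicitly defined for the lower one.

A joint is playable when the pruned span reaches `min_playable_deg`
(default 20°); unplayable joints refuse to score. The avatar position is
the target angle mapped to percent of the calibrated range and clipped to
[0, 100]. The 30 s target path is a natural cubic spline through waypoints
constrained to the [5, 95] band — the centred realization of "within 90 %
of the range" — touching ≤ 10 and ≥ 90 at least once; spline overshoot is
clamped to the band. The analysis window is the **first 25 s** of the 30 s
recording: the final seconds exist to keep the player engaged to the end,
and reading them as the last 5 s *of* the recording (rather than after it)
is the conservative choice; both numbers are arguments.

## Standardized-error scoring

The adult reference (`build_reference()`) estimates, per timepoint of the
analysis window, the SD of adult avatar deviation around the path
(σ_path, percent) and the mean and SD of each channel's derivative
(μ_c, σ_c, deg/s). Standardizing by per-timepoint adult SD reads as "how
many adult SDs away, on average", and automatically discounts locally
difficult path segments, where adults themselves spread out. Centring
derivatives on the adult mean rather than zero avoids penalizing
physiological co-movements. Two numerical choices:

* **SD floor** (default 0.5 native units): where adults are
  near-deterministic a raw SD can approach zero and blow up the ratio; the
  floor bounds scores on degenerate references. σ_path is computed on
  clipped avatar positions — what actually steered the game.
* **Standardize-then-average** is the primary order (pointwise ratios,
  then the time mean). An average-then-standardize variant is available
  via `order = "average_first"` for sensitivity analysis only.

Channel errors aggregate in two levels: within joint units (trunk lateral +
ventral; hip flexion + rotation per side; remaining joints singleton), then
across units with equal weight, the target channel always excluded. The
per-target unit tables are data (`aggregation_units()`), not code, because
only the ankle-target composition is fully pinned down externally; the
table-driven design keeps the remaining compositions editable. Missing
channels are dropped by default (unit averages run over available members);
`strategy = "fail"` refuses partial sessions, and externally imputed values
can be injected through the `imputed` hook — multiple imputation itself is
out of scope here.

If every per-timepoint quantity were exactly Gaussian and the reference
exact, an unimpaired player's channel error would converge to the mean
absolute deviation of a standard normal, √(2/π) ≈ 0.798. The test suite and
the acceptance script verify this calibration identity on a synthetic
1000-adult Gaussian cohort to within 0.03.

**Age normalization.** Children and patients are z-transformed against
neurologically intact children whose integer age is within one year of the
participant's integer age (a 7.2-year-old's peers are the 6-, 7- and
8-year-olds) — the literal reading of a ±1-year peer band around the
integer age; adults are compared against the whole adult group. Peer groups
smaller than 3, or with zero SD, yield no z-score rather than a fabricated
one. Positive z is worse.

## The simulator: what it emulates, and what it does not

`simulate_session()` produces ground-truth kinematics and renders them as
sensor streams:

* the target joint tracks the path with a lag (default study conditions:
  0.1–0.2 s for adults), smoothed Gaussian tracking noise (2–4 % of range
  for adults) and optional tremor;
* the contralateral homologue and synergy channels move with angular
  velocity proportional to the target's (gain × target derivative — the
  defining property of mirror and synergy coupling);
* the trunk sways sinusoidally (0.2–0.35 Hz);
* sensors read gravity rotated by the cumulative chain angle (sagittal and
  lateral planes composed in sequence) plus white noise, on a shared
  irregular timestamp grid alternating 29 Hz and 58 Hz segments with a
  0.7/0.3 expected time split.

The sensor-noise default is 0.005 g (≈ 0.3° of per-sample inclination
noise), consistent with the bench repeatability of the class of hardware
this models; noise is a free parameter. The gravity rendering is exact in
the sagittal plane and first-order in the lateral plane (a cosine coupling
term), which is why lateral-plane channels are reserved for small-amplitude
movements in the default tables.

Group-level profile priors (`draw_profile()`) are **synthetic, tunable
distributions that exist to exercise the scorer, not population models**:
adults draw minimal gains; intact children draw a mirror gain that decays
with age (mirror movements are physiological in young children and fade
around age 10); patients draw elevated heterogeneous gains. Consequently,
passing tests demonstrate that the pipeline recovers what the simulator
put in — they say nothing about sensitivity or specificity in real
patients, about soft-tissue artifact, sensor misplacement, magnetic or
thermal drift, or non-sinusoidal trunk behaviour, none of which the
simulator emulates.

The parameter-recovery experiment (acceptance script and test) varies the
three involuntary-movement gains that form the composite severity index
across 50 simulated participants while holding tracking behaviour fixed at
5 % noise and 0.2 s lag: tracking quality is a separate outcome dimension
(accuracy), and letting it vary would conflate the two outcomes in a check
that is specifically about involuntary-movement recovery. The composite
scales each gain by the upper end of its patient-prior range so all three
classes contribute comparably.

## Problem sizes and determinism

Simulated study conditions use 30 s sessions at 29 Hz (725 analysis
timepoints), reference cohorts of 10 adults, 20 seeds per point of the
mirror-gain monotonicity curve, 50 participants for rank recovery, and a
1000-member synthetic Gaussian cohort for the √(2/π) identity. Every random
element — paths, profiles, noise, timestamps — is driven by explicit seeds;
identical inputs give identical outputs to the byte.

## Known limitations

* Per-joint angle formulas are convention-table defaults, not validated
  against any specific hardware's internal algorithm; the table is the
  intended point of reconciliation.
* Hip rotation and forearm pro/supination rely on lateral-plane
  inclination, which degrades as the limb approaches the vertical of the
  measuring plane; the ill-conditioning guard flags rather than fixes this.
* The adult reference must be built on the identical path and grid as the
  sessions it scores; there is deliberately no cross-path normalization.
* Scores are emitted per session; longitudinal and group-level inference
  (mixed models and the like) is downstream tooling fed by the tidy CSV
  output, not part of this package.
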