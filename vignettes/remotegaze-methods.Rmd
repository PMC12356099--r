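---
title: "Models and methods in remotegaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in remotegaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`remotegaze` implements an analysis pipeline for head-tracking and
hippocampal spike data from small birds performing a discrete
visual-search task, together with a ground-truthed synthetic-session
generator used to validate every estimator. Birds direct gaze with rapid,
ballistic head rotations ("head saccades") separated by stable fixations;
they travel between feeder sites in fast, direct hops ("dashes"). The
pipeline recovers these behavioral states from 300-Hz rigid-body head
pose, derives per-eye gaze rays, and quantifies how hippocampal cells
respond to occupied locations (place tuning) and to remotely viewed
locations (gaze tuning).

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open. It states no
empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

# Reference frames and gaze geometry

Head pose is a 3D position (mm) plus a unit quaternion per sample. The
head frame has its origin at the midpoint of the two eyes, x through the
eyes (right positive), y through the beak, z up
(`head_frame_from_landmarks()`). Eye calibrations store each eye's
position and optical axis in this frame; the two optical axes are
separated by 106 degrees by default and gaze is taken 5 degrees below the
optical axis, rotated about the head x axis (`gaze_rays()`). The
underlying measurement convention states only that the offset is
"downwards"; rotation about the
inter-eye axis is the natural reading and is what we implement.

Angular deviation of gaze from a site is the angle between the gaze
direction and the eye-to-site vector (`angular_distances_to_sites()`); an
eye coincident with a site center has deviation 0 by convention. Gaze
cones are projected onto the arena floor on the same 40 x 40 grid used by
rate maps, with unit occupancy weight split uniformly over intersected
bins (`project_gaze_to_floor()`); the weighting within the cone is not
specified by the source analyses, and uniform splitting keeps occupancy
mass exactly conserved per sample.

# The synthetic-session generator

`generate_session()` emits head pose, exact per-sample state labels,
per-saccade ground truth, and closed-loop task events for the three task
variants (random, blocked-trial with catch trials, all-to-all on a
pentagon). The generator's defaults are the study conditions; they are
not tuning knobs:

* Saccade durations: truncated normal, mean 76 ms, sd 21 ms, floor 30 ms.
* Saccade velocity profile: a raised-cosine (Hann) angular-velocity
  pulse. It is smooth, unimodal, integrates exactly to the drawn
  amplitude, and gives peak speed `2 * amplitude / duration`, so the
  main-sequence relation (amplitude vs peak speed) emerges with rank
  correlation above 0.8 because amplitudes vary far more than durations.
* Inter-saccade intervals: gamma. Only the summary "instantaneous rates
  of 3.8 +/- 1.4 Hz" and a median interval near 270 ms are reported for
  the real behavior, and the distributional family is not; we resolve the
  reported rate as the reciprocal interval and choose the gamma shape
  `k = 2 + (3.8/1.4)^2` and scale `1/(3.8 (k-1))` so that `1/ISI` has
  mean 3.8 Hz and sd 1.4 Hz exactly. The implied median interval is
  about 284 ms, consistent with the "~270 ms" figure. This calibration is
  analytic, fixed before any measurement.
* Fixations aim one eye (lateral gaze) or the beak (frontal gaze) at a
  task site through the shortest-arc rotation, followed by a spin about
  the gaze line that keeps the head as upright as possible. The spin
  matters: the bare minimal rotation flips the head upside down whenever
  the target direction is nearly antiparallel to the eye's head-frame
  axis, which no bird does and which would corrupt the tilt feature.
  Fixation orientation jitter is Gaussian with sd 1 degree.
* Ocular scatter: on top of the jitter, each fixation's head orientation
  misses the exact aim by a random rotation with sd `eye_in_head_mad`
  (5.4 degrees) -- the eye foveates the target, so the fixed head-frame
  mean eye axis is off by the eye-in-head deviation. This scatter is
  load-bearing: with exact aiming, the angular distance of the
  contralateral eye to a site and of the ipsilateral eye to the adjacent
  site become deterministic functions of each other (90-degree site
  spacing against a 106-degree inter-eye angle), the two GLM regressors
  collapse into near-perfect collinearity, and contralateral-vs-
  ipsilateral attribution is undecidable in principle. Real eyes move in
  the head; the scatter restores the variation that makes the separation
  identifiable, though per-cell attribution remains noisy and population
  medians are the robust summary.
* The last fixation before each dash is frontal toward the dash target;
  earlier fixations are lateral scans. This gives the gaze-strategy
  analysis (`classify_gaze_strategy()`) a recoverable
  lateral-then-frontal structure.
* Dashes: straight-line segments at 1100 mm/s with 80-ms smoothstep
  ramps (trapezoidal speed). Hops between perches accelerate briskly;
  a long sinusoidal ramp would leave the bird loitering at take-off
  speed near the perch, which neither real hops nor the segmentation's
  dash definition do.
* Feeding: 0.4-1.2 s bouts with the beak pitched 60 degrees down (the
  feeder cup sits below the perch), reached through a 0.3-s ramp.
* The closed-loop controller monitors the generated gaze with the same
  consecutive-run detector exposed as `detect_gaze_trigger()`: the light
  turns on when an eligible eye stays within the trigger threshold
  (10-20 degrees, default 15) for at least 3 samples, after a 40-ms
  latency. Catch trials withhold the light on the first detection only.
  Blocked sessions repeat each target for 6 trials with 2 catch trials
  placed to keep session-wide within-block positions balanced to +/-1.
* All randomness derives from one session-level seed.

What the generator does not emulate: tracking dropouts and marker
occlusions, postural drift, continuous within-fixation eye movements
(ocular scatter is drawn once per fixation and expressed through the
head orientation, while the analysis-side eye calibration stays fixed,
as in the real measurement chain), reaction-time variability in leaving
the perch, and exploratory excursions off the site-to-site paths. Passing tests on synthetic data
therefore demonstrate correctness of the estimators under the stated
statistical structure, not robustness to every artifact of real
recordings.

# Spike generation

`rate_function()` builds an inhomogeneous rate (Hz) per neuron:
baseline, plus a Gaussian spatial field (sd 80 mm) at the preferred site
expressed while dashing, plus per-saccade gaze kernels: an early
(predictive) Gaussian bump at +17 ms (sd 25 ms) and a late (visual) bump
at +187 ms (sd 40 ms) after peak saccade velocity, each scaled by the
Gaussian angular closeness `exp(-alpha^2 / (2 tau^2))` (tau = 45 degrees)
of the landing gaze to the preferred site. Gaze drive mixes the
contralateral eye with weight `contra_fraction` (default 1) and the
ipsilateral eye with the complement. The late bump is multiplied by
`light_modulation` when the light is on at the time of the bump, the
early bump by `prediction_modulation` when the target is expected
(blocked task). We attribute both bumps to the saccade's own landing
fixation -- the late response is the visual reaction to the newly fixated
target, the early response its prediction -- and expose
`early_prev_dep`/`early_next_dep` exponents so that the early response
can be made to depend on the previous gaze, the next gaze, or both (the
three hypothesis patterns of the bivariate analysis). Interneuron types
instead carry a saccade-entrained quasi-oscillation (period 270 ms,
envelope sd 250 ms) whose phase at +187 ms is `phase_offset` (0 for peak
cells, pi for trough cells). Rates are floored at zero; this
rectification is a deliberate deviation from log-additivity and is the
only point where the generator departs from the GLM's exponential link.

Spikes are sampled per 3.33-ms sample as Poisson counts at the
piecewise-constant rate with uniform placement within the sample, which
is exact for piecewise-constant rates. Mean waveforms are parametric
trough-plus-two-peaks templates with class widths 0.51 / 0.27 / 0.33 ms
and asymmetries -0.04 / 0.55 / 0.56, so the waveform classifier is
exercisable end to end.

# Behavioral segmentation

Features (`compute_kinematic_features()`): linear speed from finite
differences of position, angular speed from shortest-arc quaternion
differences, both zero-phase filtered with a 2nd-order Butterworth at
25 Hz (zero-phase so refined event times are not lag-biased); head tilt
(angle of head z from vertical); and Gaussian proximity
`exp(-d^2/(2*50mm^2))` to each site and each permitted inter-site path.
Speeds enter the HMM as `log10(1 + x)`: saccade speed spans more than an
order of magnitude with amplitude, and a log scale lets small and large
saccades share one Gaussian state.

The HMM (`hmm_spec()`) has fixation/saccade/feed states at each site and
one dash state per ordered permitted pair. Means are initialized from
arena geometry and kinematic priors and may be refit by Viterbi training
(`fit_observation_means()`, decode and re-estimate means until labels
stabilize); the full-EM alternative is not implemented -- the source
describes iterative mean fitting without specifying the scheme, and
Viterbi training matches the decoding actually used. Variances and the
transition matrix are fixed. Self-transitions are 0.99 with the remainder
split over permitted moves; beyond fixation-saccade, fixation-dash,
dash-feed/fixation and feed-fixation we also permit saccade-feed and
saccade-dash. Without those two, a Viterbi path can never produce the
"saccade immediately preceding feeding" and "saccade immediately
following a dash" sequences that the published cleanup rules exist to
repair, so the rules would be dead code. Dash states take proximity
means of 0.5 at their endpoints and 1 along their own path: a dash
occupies its entire segment, not just its midpoint.

Decoding is exact Viterbi in C++ (`viterbi_decode()`), validated against
exhaustive enumeration on small instances. Cleanup and refinement
(`refine_segments()`) apply, in order: saccades before feeding merged
into the feed, saccades after a dash merged into the dash, feeding after
a dash merged into the dash; then saccade endpoints are trimmed to the
outermost samples where angular speed >= 400 deg/s OR absolute angular
acceleration >= 5000 deg/s^2 (OR, so the acceleration criterion catches
slow tails), and dash stop times are moved to the 150 mm/s / 3000 mm/s^2
crossing -- extended forward when deceleration was decoded into the
following state, not merely trimmed back. A decoded "saccade" containing
no sample at or above the velocity threshold is discarded and absorbed
into its neighbor: single-sample decode blips at dash onsets pass the
acceleration criterion purely through finite-difference jumps, and an
existence requirement on the velocity crossing removes them without
touching genuine saccades. Durations are the span between the outermost
supra-threshold samples.

Landing sites are assigned from the eye-gaze deviation sampled ~20 ms
into the following fixation (within 20 degrees); saccades followed by a
fixation are analysis-eligible, and those that landed on a site more than
0.5 s before the next dash form the gaze-analysis inclusion set. Sessions
need at least 5 dashes and 5 included saccades per eye per outer target
(`session_inclusion()`).

# Tuning statistics

Site information (`site_information()`) is
`I = sum_x (lambda(x)/lbar) log2(lambda(x)/lbar) p(x)` in bits/spike with
`0 log 0 = 0`; cells with zero overall rate are flagged, not errored.
Place responses are mean rates in +/-1 s windows around dash ends; gaze
responses are counts in [-0.1, +0.3] s around peak saccade velocity over
the inclusion set. Significance comes from 200 label permutations
(per-site event counts preserved -- a permutation, not a resample, which
the source wording leaves open); a cell is significant when its
information exceeds 99% of shuffles, and the reported p-value is
`(1 + #{shuffles >= actual}) / (n_shuffles + 1)` so it can never be zero.
Normalized information divides by the shuffle mean.

Rate maps use a 40 x 40 grid over the arena; place maps smooth counts and
occupancy with an 11 x 11 Hamming kernel (unit sum; at edges and outside
the visited mask the kernel is renormalized, trading exact mass
conservation for unbiased edge rates), gaze maps use 9 x 9 smoothing of
cone-projected occupancy. The place-map spike-behavior delay is searched
over -0.3 to +0.3 s in 33.3-ms steps (the source says only "a range of
delays"), keeping the offset that maximizes map information. Preferred
sites are the largest response with ties broken toward the lowest index;
the selectivity index is 1 minus the second-largest normalized response.

# The gaze GLM

The design (`build_gaze_design()`) has one row per included saccade:
counts in [-0.1, +0.3] s against eight regressors, the Gaussian basis
`exp(-alpha^2 / (2 tau^2))` (tau = 45 degrees) of the angular distances
of the four outer sites from the contralateral and ipsilateral eye's
gaze at the landing fixation. The typeset source formula is ambiguous
between a `tau^2` and a `2 tau^2` denominator; the standard Gaussian
`2 tau^2` is the default and a switch (`denom_2tau2 = FALSE`) provides
the alternative for sensitivity checks. Both eyes enter every row --
birds sometimes fixate two sites with different eyes simultaneously, and
separating those contributions is the model's purpose. Fitting
(`fit_poisson_lasso()`) minimizes the Poisson negative log-likelihood
plus an L1 penalty of 0.005 on the eight coefficients via `glmnet`
(alpha = 1), intercept unpenalized, regressors unstandardized (the basis
is already bounded in (0, 1]). Coefficients are not rectified; the
normalized difference `(c - i)/(c + i)` is flagged undefined when
`c + i = 0`. With the penalty at zero the fit agrees with an unpenalized
Poisson regression to 1e-6, which the tests verify against `stats::glm`.

The light-state control fits counts on site identity and light state and
tests each factor with a likelihood-ratio chi-square. The all-to-all
analysis forms baseline-subtracted target and source curves (dash:
+/-0.5 s around the dash end minus -2 to -1 s; saccade: 0 to +0.3 s minus
-1 to -0.2 s), requires four events per ordered source-target pair, and
summarizes selectivity as curve maximum minus curve mean.

# Saccade-aligned dynamics

PSTHs bin spikes at 3.33 ms and smooth with a Gaussian kernel (30 ms sd
for gaze responses, 100 ms for dash responses) truncated at 4 sd and
renormalized at window edges; the unsmoothed mean is kept alongside, and
the raw PSTH integral times the event count equals the in-window spike
count exactly. Early and late response peaks are the maxima within
+/-50 ms windows centered at 17 and 187 ms; populations are sorted by
their difference. The bivariate early-response analysis bins the angular
distances of the flanking gazes in 10-degree bins and exports the matrix,
its marginals, and the conditional slice with the previous gaze clamped
to 30-40 degrees. The early-response linear model uses the eight gaze
deviation covariates (horizontal, vertical, and squares, before and
after) with fixed-effect per-cell intercept dummies -- exact and
solver-agnostic, where a random-intercept mixed model is the source's
choice; coefficients are Bonferroni-corrected over eight tests.

# Cell types

Four waveform features (log rate, trough-to-peak width, flanking-peak
asymmetry, log derivative peak/trough ratio) feed a two-component
Gaussian mixture (via `mclust`, full covariances, with simpler
covariance fallbacks for small fit sets). The component with the lower
mean log rate is excitatory. Cells farther than Mahalanobis distance 3
from both components are unclassified; the threshold value is
unpublished, and 3 is our default. Note that in four dimensions a
distance-3 cutoff leaves about 6% of genuine members unclassified
(chi-square-4 tail), so recovery statistics are reported among classified
cells.

Interneuron phase is the analytic-signal (FFT Hilbert) phase of the
mean-subtracted saccade-aligned rate at +187 ms; mean subtraction is
required for a meaningful analytic signal and is applied over the whole
analysis window. Circular k-means (k = 2, 10 restarts, best objective
kept) splits phases into peak and trough groups, labeled by the sign of
the standardized response at +187 ms; a partition-agreement stability
score across restarts flags degenerate (uniform) phase distributions.

# Problem sizes and checks

The test suite builds all fixtures in code: a 240-s synthetic session
with its segmentation is shared across files, and the heavier acceptance
checks use two 600-s sessions (segmentation round trip), one 600-s
session with 60 gaze-tuned cells (length-constant recovery), 2000 null
cells with 200 shuffles each (type-I calibration), and a 400-event
isolated-saccade session (biphasic latency recovery, judged by the
baseline-subtracted centroid of each bump, whose precision scales with
the number of bump spikes where a raw argmax on a 25-ms-wide bump cannot
resolve one 3.33-ms bin). `scripts/acceptance.R` runs the full-scale
versions: ten 30-minute sessions for the behavioral statistics and one
30-minute session with 200 cells for the decay fit, with every random
draw derived from the `--seed` argument. In the decay fit, distance bins
are weighted by their saccade counts: sparse bins are dominated by
landing-measurement noise and carry little evidence.

# Known limitations

* The generator's behavioral repertoire is schematic (no off-path
  exploration, fixed eye-in-head axes, deterministic trigger latency at
  the reported median).
* Viterbi training can drift observation means toward the decoded
  boundaries; we cap refitting at a few iterations and keep variances
  and transitions fixed, but strongly misspecified priors are not
  self-correcting.
* Dash-boundary samples are genuinely ambiguous between "perched at the
  site" and "moving"; per-sample agreement with ground truth is about
  94% on default sessions, with the residual concentrated in the first
  and last few samples of dashes.
* The interneuron quasi-oscillation is a single-frequency caricature of
  saccade-entrained inhibitory dynamics; it is sufficient to test phase
  estimation and clustering, not a model of the underlying circuit.
* The package provides no shell entry point: the functions, the
  `run_pipeline()` driver and the documented CSV/YAML readers and
  writers are the interface, since its users drive analyses from R.
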