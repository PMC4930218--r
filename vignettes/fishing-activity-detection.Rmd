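---
title: "Detecting fishing activity from AIS tracks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fishing activity from AIS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gearsense)
```

gearsense labels every AIS position report of a fishing vessel as fishing
(`F`) or non-fishing (`NF`), with a separate method per gear type because
trawlers, longliners and purse seiners move in kinematically different
ways while fishing. This vignette is the package's own account of the
three models, the parameters that matter, what the synthetic-track
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## Shared preprocessing

All detectors consume a *track*: a time-ordered sequence of reports with
speed over ground (SOG, knots). Two derived features are attached by
`annotate_track()`:

* **Distance to shore** (`shore_km`): the minimum haversine distance to a
  set of shoreline vertices, on a sphere of radius 6371.0 km. Points
  closer than `offshore_km = 10` km are treated as out-of-domain and
  forced `NF` — vessel movement near port (maneuvering, anchoring,
  drifting) mimics fishing kinematics too easily. The computation is
  vertex-based, so shoreline resolution bounds its accuracy: with
  vertices 10 km apart the error can reach half the spacing. A denser
  vertex set, not a segment-based distance, is the intended remedy. The
  default scan finds the nearest vertex by 3-D chord length (a monotone
  transform of the central angle, hence the same minimizer) and is
  verified in the tests to return the identical value as the exhaustive
  haversine scan.
* **Daylight** (`is_day`): true iff the solar elevation at the point's
  position and instant is positive, computed with a low-precision solar
  ephemeris (fractional-year Fourier series for declination and the
  equation of time). Twilight and refraction count as night by default;
  a `refraction` flag moves the threshold to −0.833°. The implementation
  agrees with an independent Astronomical-Almanac-style calculation to
  within ±5 minutes of sunrise at |lat| < 60°, which is ample for gating
  fishing activity by daylight.

`regularize_track()` resamples a track onto a fixed grid (default 7 h) by
linear interpolation of latitude and longitude between the bracketing
fixes, splitting the track wherever consecutive fixes are more than 24 h
apart rather than interpolating across a coverage gap. Interpolation was
chosen over subsampling because at a 7-hour step the nearest original fix
can sit hours away from the grid instant; both behaviors are available
(`mode = "subsample"`). Positional error from interpolating in coordinate
space rather than along great circles is negligible at this step length —
vessel behavior, not geometry, dominates. Grid speed is the great-circle
displacement per step in knots; it is a *net displacement* rate, which is
exactly the property the longline pipeline needs (a vessel working a line
back and forth has high instantaneous speed but low net displacement).

## Trawler: a supervised two-state speed HMM

Trawl tows are slow (2.5–5.5 kn) and steady for 3–5 h, well separated
from steaming speed. The model is a first-order hidden Markov chain over
S_t ∈ {F, NF} with SOG as the observation; the joint of a state
sequence is Pr(S_1)·Pr(Y_1|S_1)·∏ Pr(Y_t|S_t)·Pr(S_t|S_{t−1}). Training
is fully supervised (`fit_trawler_hmm()`): transition probabilities are
row-normalized counts of consecutive label pairs, pooled across tracks
but never across a track boundary, and the initial distribution is the
empirical label frequency.

The emission family is a deliberate choice: real fishing/non-fishing
speed distributions are skewed and multi-modal, so the default is a
binned histogram (bin width `w = 0.5` kn, support [0, 25.5] kn — the AIS
speed-field saturation convention — additive smoothing `alpha = 1`
pseudo-count per bin so unseen speeds never have zero probability).
A Gaussian emission is offered for small training sets, where 51 bins
per state would be under-determined. Speeds above `v_max` clip into the
top bin. The 2.5–5.5 kn trawl envelope is *not* hard-coded into the
model — the HMM commits only to speed as its observation; the envelope
informs the simulator.

Decoding (`decode_trawler()`) is Viterbi in log space by default, since
the deliverable is a per-point label sequence; posterior (forward–
backward marginal argmax) decoding is available and tends to maximize
per-point accuracy rather than sequence plausibility. Ties break toward
`NF`, the conservative call. Zero-probability emissions (possible with
`alpha = 0`) are floored at `log(1e-300)` and reported rather than made
fatal. Viterbi is verified against exhaustive enumeration of all 2^T
sequences for T ≤ 8 over hundreds of random models.

## Longliner: regularize → segment → straightness → FPT → UD

Longline speed distributions barely separate fishing from transit, so the
pipeline (`detect_longline()`) works on movement geometry at the scale of
a fishing operation:

1. **Regularization** at `step_hours = 7` — the scale of a longline set
   (median set duration 6.5 h).
2. **Segmentation.** The per-step displacement series is partitioned into
   K contiguous segments minimizing the least-squares contrast
   Σ_seg Σ_i (x_i − x̄_seg)², solved *exactly* by dynamic programming
   (`lavielle_segment()`, minimum segment length 2, ties to the earliest
   breakpoints). The displacement signal is a design choice — the
   quantity whose mean shifts between transit and area-restricted fishing
   — with raw grid speed available as an alternative. The reference
   segment count K = 70 was calibrated on multi-month commercial tracks;
   `detect_longline()` scales it with track length as
   `max(2, round(70 · n_steps / N_ref))` with `N_ref = 1900` steps
   (about 18 months at 7 h), so a 70-segment prior on a long track
   becomes a proportionally coarser prior on a short one. `K` can be
   fixed explicitly.
3. **Straightness.** For each segment, the mean cosine of the turning
   angle between consecutive displacement vectors (local planar
   projection per vertex; zero-length displacements count as "no turn").
   |mean| > 0.8 marks straight-line movement — persistent forward motion
   (mean near +1) *or* exact retracing (mean near −1) — and the segment
   is labeled `NF` wholesale. The mean-cosine rule is primary because it
   is the only quantified form; a per-point majority variant
   (`straight_mode = "majority"`) is provided. Segments too short to
   have an interior (< 3 grid points) are conservatively non-fishing.
4. **First-passage-time filter.** Curved segments become fishing
   candidates, then FPT analysis removes slow meanders that are not
   area-restricted: FPT(i; r) is the time the path takes to cross a
   circle of radius r centered on point i (forward crossing minus
   backward crossing, crossing instants linearly interpolated; undefined
   if the path never exits the circle in one of the directions within
   the segment). With 30 radii uniform on [0.1, 1] coordinate degrees
   (the convention of operating in coordinate units; km available), the
   segment stays fishing iff max_r Var_points(log FPT(r)) > 0.1.
   The variance is taken per segment across points and maximized over
   radii — the variance-peak usage of FPT analysis; the grouping is
   ambiguous in the field's usage and this reading is the one that makes
   the 0.1 threshold act at the segment level where the decision is
   made. Fewer than 5 defined FPTs is a degenerate segment, conservatively
   `NF`.
5. **Utilization-distribution correction.** A bivariate normal-kernel
   density with normal-reference bandwidths is evaluated over all
   surviving candidate positions (pooled across segments by default;
   per-segment optional), and points below the 5 % density quantile —
   outside the 95 % isopleth, the home-range convention — are demoted to
   `NF`. No isopleth value is canonical for this correction; 0.95 is
   exposed as `ud_isopleth`. Fewer than 10 candidates, or zero spatial
   spread, makes the correction a no-op.

Grid labels are mapped back to the original reports by nearest-in-time
assignment within half a step; shore-masked points are forced `NF` last.
The pipeline is monotone by construction: after segmentation every filter
only ever demotes fishing candidates, never promotes.

## Purse seiner: daylight ∧ offshore ∧ slow

`detect_seiner()` is a pure per-point predicate: `F` iff daylight (unless
day-gating is disabled), `shore_km ≥ 10`, and `sog ≤ 2.5` kn. Both
boundaries are inclusive on the fishing side: 2.5 kn is explicitly
fishing; at exactly 10 km the point counts as offshore (the ambiguous
case, resolved inclusively so the offshore threshold never overrules the
two behavioral clauses on the boundary itself). The filter captures the
haul/bailing phase only — the high-speed net-setting dash is too brief to
be reliably sampled by satellite coverage. There is no minimum-duration
clause by default (`min_event_minutes = 0`), keeping the filter
per-point; the post-filter exists for users who want to suppress isolated
slow fixes.

## The synthetic-track generator

The simulator exists because the S-AIS tracks the methods were developed
for are proprietary. It generates labeled tracks per gear from the
operational definitions of fishing — the quantities that *are* published:

* trawler: steam/trawl alternation, trawl speeds uniform on 2.5–5.5 kn
  with tow durations uniform on 3–5 h;
* longliner: straight set legs slightly slower than steaming with
  log-normal durations (median 6.5 h), a station-keeping soak under 2 kn
  near the line end, and a haul that retraces the set leg at reduced
  speed — so fishing is area-restricted at the 7-hour scale while sets
  themselves are straight; trips place 1–4 consecutive set cycles on a
  ground, as longliners work an area for days;
* seiner: daylight-gated hauls at ≤ 2.5 kn lasting 1–4 h between
  high-speed search legs; night phases (steam or drift) end at dawn and
  hauls end at sunset, so the day-only definition of seine fishing is
  internally consistent.

Everything not published as a parameter is a declared surrogate chosen
for realism, recorded in `gear_profile()`: steaming speeds (truncated
normals; the trawler's N(10.5, 3) deliberately overlaps the trawl band so
the HMM is tested under emission overlap, not on a separable toy),
reporting intervals (gamma, mean 5 min), coverage gaps (2 % of reports
open a 0.5–3 h hole), GPS noise (50 m). Reported SOG is the true phase
speed; positions carry the noise. Phase boundaries of the longline set
and haul are explicitly reported — a vessel pauses at deployment and
turnaround — which is also what makes the retrace invariant testable on
reported data. One seed drives schedule, kinematics, noise and gaps;
tracks are bit-reproducible.

What the generator does **not** emulate: currents and drift during soak
(station-keeping is idealized), bathymetry or fish-density fields, port
calls and shore-adjacent behavior, multi-vessel interaction, AIS
spoofing, or the heavy-tailed empirical speed distributions of real
fleets. Passing on synthetic tracks therefore demonstrates algorithmic
correctness under each detector's own behavioral model — not field
accuracy on commercial fleets, which can only be established against
expert-labeled or observer-verified AIS data.

## Evaluation conventions

`confusion_metrics()` follows the reporting convention of the validation
tables this work mirrors: **sensitivity is the recall of non-fishing and
specificity the recall of fishing**; `prediction_F`/`prediction_NF` are
the class-wise precisions, read as the expected correctness of each
predicted label on unseen data. Undefined ratios (a class absent from
truth or prediction) are `NA`, never 0. For hard labels the AUC is the
trapezoid through the single operating point, (sensitivity +
specificity)/2; with continuous scores the rank-based Mann–Whitney AUC is
used instead. These constructions are this package's documented readings;
the identity accuracy = pct_F·specificity + (1 − pct_F)·sensitivity is
enforced in the tests to 1e−12.

Fishing effort is the per-event duration between the first and last
report of each maximal `F` run; predicted and reference effort are
compared with a Welch (unequal-variance) two-sample t-test — the
conservative default when only "a t-test" is specified — with `NA` when
either side has fewer than two events.

`monte_carlo()` evaluates the trainable detector under time variation:
for each training size it draws one window start per equal stratum of the
feasible range (so windows dislocate forward and test stretches are not
reused), trains on the window and predicts the following points.
Defaults are 20 windows; window sizes requested beyond the data are
scaled down proportionally with a warning.

## Numerical choices and degenerate inputs

* Lavielle DP uses cumulative sums for O(1) segment costs and resolves
  exact cost ties (within a 1e−9 relative band) toward the earliest
  breakpoint vector, making segmentations deterministic.
* Viterbi and the log joint are computed in log space; forward–backward
  is scaled per step, with fully-floored steps (all-zero likelihood)
  treated as uninformative rather than NaN.
* Duplicate timestamps keep the first report; unparseable rows are
  rejected with their row numbers reported; labels outside {F, NF} are
  demoted to unlabeled with a warning (fail-soft on partly labeled
  files).
* Tracks too short to regularize, segments without defined FPTs,
  candidate sets too small or too concentrated for a kernel density —
  all resolve to non-fishing with a logged message, so every degenerate
  path errs toward the conservative label.
* Model JSON serialization writes doubles at 17 significant digits, so a
  written and re-read HMM is bit-identical.

## Problem sizes in the shipped tests

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute: simulated voyages of 600 h
(trawler, ≈ 5,200 reports), 900 h (longliner, ≈ 7,400 reports) and 8–12
days (seiner, ≈ 2,000 reports); Monte Carlo at 20 windows of 2,000
training and 5,000 test points; exhaustive-enumeration oracles at T ≤ 8
(HMM) and n ≤ 40, K ≤ 4 (segmentation). These sizes exercise every code
path at full statistical strength for the properties being checked;
nothing in the implementation is specific to them.

## Known limitations

Beyond the simulator's idealizations listed above: the longline K-scaling
rule is a linear heuristic and the segment count remains the pipeline's
most sensitive input; distance-to-shore accuracy is bounded by shoreline
vertex density; antimeridian-crossing tracks are only handled by
splitting at ±180° jumps; and the HMM is strictly two-state and
supervised — no Baum–Welch, no additional behavioral states.
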