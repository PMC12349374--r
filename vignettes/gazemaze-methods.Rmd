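---
title: "Gaze-controlled maze therapy monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-controlled maze therapy monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemaze)
```

`gazemaze` re-creates the software side of a gaze-controlled maze therapy
device for amblyopia as an offline, fully testable toolkit. This vignette
is the package's own account of its models, conventions and numerical
choices; it is the place to look when a default seems arbitrary or a
convention surprising.

## Gaze model

### Coordinates and landmarks

All positions are normalized image coordinates with **y increasing
downward** — the convention of landmark streams produced by face-mesh
detectors. One frame carries, per eye, four iris-contour points and four
eye-contour landmarks (outer corner, inner corner, upper and lower
eyelid). The package never sees pixels: landmark inference happens
upstream, behind the JSONL stream boundary, and is explicitly out of
scope.

### Pupil localization

The pupil is the center of the *minimum enclosing circle* of the four
iris points. The enclosing circle is computed by Welzl's recursive
algorithm with exact handling of the 1-, 2- and 3-point boundary cases
(diameter circles are preferred over circumcircles when a pair already
covers the third support point; collinear triples fall back to the widest
pair). Input is capped at 16 points — far above the 4 the pipeline uses —
and points within `1e-9` of the boundary count as enclosed. The test
suite checks the implementation against an exhaustive brute-force oracle
(all pair-diameter and triple-circumcircle candidates) on thousands of
random point sets.

### Displacement ratios

Gaze direction is summarized by two dimensionless ratios per eye:

- **lateral**: horizontal pupil-to-outer-corner distance over eye width,
  in `[0, 1]` (0 = outer corner, 1 = inner corner);
- **anteroposterior**: vertical pupil-to-upper-eyelid distance over eye
  height, *negated*, in `[−1, 0]` (0 = upper lid, −1 = lower lid).

Distances are axis projections (`|Δx|`, `|Δy|`), not Euclidean, matching
the horizontal/vertical construction the ratios represent. The
anteroposterior sign is a deliberate choice between two readings that
both place mid-eye gaze at magnitude 0.5: we adopt
`−(pupil-to-upper)/height`, which reproduces the negative values these
ratios conventionally take in session tables (means near −0.5).

A pupil that lands marginally outside the contour box — routine under
landmark jitter — is **clamped** to the legal range with a per-frame
warning rather than rejected; a streaming consumer should not die on one
noisy frame. Zero eye width or height is a hard error: that geometry is
unusable, not noisy.

In binocular mode (`"Bin"`) both eyes are tracked and the binocular
signal is the pointwise arithmetic mean. In monocular modes (`"Mon-Izq"`,
`"Mon-Der"` — the occluded-healthy-eye therapies) only the therapy eye is
populated; the occluded eye's fields are *absent* (`NA`), never zero.
Export layers render absence as `-` (extremes tables) or `0.00` (segment
tables) to match the conventional printed layouts. A consequence worth
knowing: binocular extremes are extremes *of the mean signal*, so when
the two eyes' minima do not co-occur in time the binocular minimum is
strictly greater than the mean of the per-eye minima.

## Zone control

The controlling signal (binocular mean, or the therapy eye) is classified
against a central rectangle in ratio space: strictly inside both bands is
`STAY`; otherwise the axis with the larger band-normalized deviation
`|dev|/band` issues the command, with ties resolved to the lateral axis.
This rectangular five-zone reading is an implementation choice — the
underlying device documents the five zones but not their borders — and
was picked because it is deterministic, exhaustive and mutually
exclusive.

Defaults (centers 0.5/−0.5, half-width 0.12) are shipped configuration,
not calibration. `calibrate_thresholds()` overrides them from ≥ 10
central-fixation samples: centers are per-axis medians (robust to
blinks), half-widths `max(margin, k·IQR)` with `margin = 0.10`,
`k = 1.5`, so jitterier users get proportionally wider dead zones with a
floor for very steady ones. The 40–50 cm distance gate is inclusive at
both endpoints.

## Maze engine

The maze is a discrete cell grid (the physical display is 128 × 64; the
shipped fixtures use smaller grids for clarity) with walls, a start cell,
a finish region and numbered zones. Three ordered checkpoints per level —
two zone ids plus the finish — carry the timing structure, with the fixed
level mapping {1: 2,4,F; 2: 3,7,F; 3: 6,11,F; 4: 3,7,F; 5: 9,6,F}.

Collision semantics: **one error per tick whose move is blocked**,
including continuous pressing against a wall. The original collision
granularity is not documented; per-blocked-tick counting was chosen
because it is deterministic and replayable from the command log (the test
suite replays logs through an independent single-step interpreter and
compares counts). Checkpoint times are measured from *level* start, and
all times are exactly `ticks × tick_ms`. Aborted levels (command stream
exhausted) record progress so far with an `NA` total.

No debouncing of rapid zone flips is applied by default — no smoothing is
documented for the original control loop — but a majority-vote window can
be layered on the command stream by the caller.

The five fixture layouts are **synthetic**: the original five mazes were
never published (only one level's zone distribution appears as a figure),
so the package ships purpose-built stand-ins of increasing complexity
whose zone numbering covers the published checkpoint ids (level 3 has 11
zones). They are versioned JSON under `inst/extdata/mazes/`.

## Session metrics

- **Displacement extremes** per signal (`LD`, `AD`, `LI`, `AI`, `LB`,
  `AB`): plain max/min over the trace.
- **Ellipse**: center at the per-axis midpoints, semi-axes the
  half-ranges; its area `π·a·b` is zero iff a signal is constant.
- **Performance ratio**: `total_ms / errors`, rounded to 2 decimals,
  computed from *unrounded* totals. Re-deriving ratios from a printed
  table's rounded totals reproduces them only to ±0.02 — the residual of
  the table's own rounding — which is exactly what the acceptance checks
  assert. Zero errors yield an undefined ratio, exported as an empty
  cell, never infinity.
- **Segment statistics**: sample mean and **sample (n−1) standard
  deviation**, CV = 100·SD/|mean| (so CVs of negative-mean
  anteroposterior signals print positive, and CV is invariant under sign
  flips). The n−1 convention is validated end-to-end by the usability
  aggregate (75.6 ± 9.09 reproduces only with n−1). Segment windows
  HD/HI/V are derived from the level's checkpoint times —
  `[0, CHKP1]`, `(CHKP1, CHKP2]`, `(CHKP2, finish]` — since no precise
  segment boundaries are documented; this is the package's convention.

## Reports

Weekly progress regressions are ordinary least squares of per-session
totals (time, errors) on session index, via `stats::lm` behind the module
surface. `r_squared` is `1 − SS_res/SS_tot` (defined as 0 for a constant
response), and the slope p-value is the **two-sided** t test with n−2
degrees of freedom — sidedness is unstated upstream, and two-sided is the
conservative default. Per-session aggregation (rather than per-level) was
chosen for the trend plots.

The validation ANOVA is the standard balanced two-factor fixed-effects
decomposition with interaction (`stats::aov`), requiring ≥ 2 replicates
per cell and erroring on unbalanced designs (the validation protocol is
balanced by construction: trials × users × movement axes). A constant
response makes every mean square a 0/0 form; the package reports F = 0,
p = 1 — no variance, no evidence. Published F/p values from real
participants are *not* reproduction targets: the raw recordings behind
them were never released, so the package asserts formulas and structure,
not those numbers.

Fixation-validation tables pool all frames of an axis's trials per user
and variable. Whether the original analysis pooled dwell segments or
summarized them separately is not documented; pooling was adopted as the
simplest convention, with the consequence that the variable aligned with
the exercised axis reflects the spread of its three fixation targets
while orthogonal variables isolate tracking noise.

Report bundles serialize every number to `report.json` next to the
figures, so tests and downstream consumers assert on data, never on
rendered pixels. Given identical inputs the bundle is byte-identical.

## Usability scoring

Standard SUS: odd items score `value − 1`, even items `5 − value`, summed
and scaled by 2.5; categories are `≤ 50` Unacceptable, `≤ 68` Marginal,
`> 68` Acceptable. Cohort aggregation uses the arithmetic mean and n−1
standard deviation; the acceptance and unacceptable rates are
**truncated** (not rounded) to two decimals and the marginal rate is the
complement — the convention that turns 13/15 into 86.66% / 13.34%.
Item-derived scores are always multiples of 2.5; ingested precomputed
scores off that grid are flagged (attribute `off_grid`) rather than
rejected, since survey tables in the wild do contain them.

## Synthetic data generator

The generator is the inverse of the gaze construction: programmed
(lateral, anteroposterior) ratios place the pupil inside a fixed eye
geometry and the iris is rendered as four points on the iris circle, so
the estimation pipeline recovers the programmed ratios *exactly* in the
noise-free case (this is asserted at 1e−9, and holds to machine
precision).

Noise is Gaussian jitter on the **pupil position**, not on the ratios, so
it propagates through the real estimation formulas. `noise_sd` is
expressed in ratio units and scaled by eye width/height into position
units, which keeps the predicted ratio-space propagation exactly
`noise_sd` — the round-trip check at σ = 0.01 over 10,000 frames asserts
the recovered RMSE within 20% of that prediction.

Default geometry: eyes of width 0.12 and height 0.06 in normalized image
units, iris radius 0.02 — proportions typical of a face-mesh detection at
the therapy distance. Default sampling rate is 30 Hz (a camera-typical
value; the original stream rate is not documented) and is configurable
everywhere. Every entry point takes a seed; there are no unseeded
generators, and a fixed spec reproduces byte-identical output.

The fixation protocol emulates the five-point validation: per axis, three
10 s dwells (top/center/bottom, or right/center/left, the center shared),
repeated five times per axis. Default targets are ±0.25 around center —
inside the legal range with comfortable margin so that noise never
clamps.

The maze bot plans a BFS shortest path through the level's checkpoints to
the finish, then splices scripted wall-bump commands at chosen ticks, so
`errors == nrow(collision_script)` and
`total_ms == (path + bumps) × tick_ms` hold exactly; that gives the
engine, metrics and report layers a fully known ground truth.

### What the generator does and does not emulate

It emulates the *geometry* of the estimation problem — landmark layout,
ratio construction, additive tracking jitter, non-co-occurring binocular
extremes, scripted session outcomes. It does **not** model saccades,
microsaccades, drift or tremor dynamics, blinks, head motion, or
photometric effects; passing tests therefore demonstrate correctness of
the computations on well-formed landmark streams, not robustness of
landmark inference on real faces.

## Numerical choices and problem sizes

- Enclosing-circle boundary tolerance `1e-9`; degenerate (collinear)
  circumcircles detected at `1e-14` on the doubled signed area.
- Ratio clamping at the legal-range boundary; clamp events warn.
- Ties in zone classification resolve to the lateral axis.
- Regression on a constant response returns slope 0, `r_squared` 0,
  p = 1 rather than NaN; numerically perfect fits return p = 0 for a
  non-zero slope.
- The verification workloads are sized to be decisive yet quick: 1000
  random point sets (≤ 8 points) for the geometry oracle, 500 noise-free
  plus 10,000 noisy frames for the gaze round trip, five maze levels with
  1–5 scripted collisions, and 200 seeded ANOVA simulations (4 users × 2
  movements × 5 replicates, injected user effect ≈ 1.5 σ) for the
  detection-rate check.

## Known limitations

- The rectangular zone geometry and the checkpoint-based segment windows
  are package conventions where the original device's exact definitions
  are undocumented; both are stated in the I/O schema and above.
- Head-pose compensation is out of scope (as it is for the original
  prototype); the gaze model assumes a stationary head.
- Real patient-level session values are not reproducible from published
  material; the package reproduces their schemas, formulas and
  qualitative relationships instead.
- The maze fixtures are synthetic stand-ins, suitable for testing and
  simulation, not replicas of the original level layouts.
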