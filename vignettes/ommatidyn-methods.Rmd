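---
title: "Quantifying ommatidial rotation and tissue fluidity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ommatidial rotation and tissue fluidity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatidyn)
```

## The system and the measurements

During *Drosophila* pupal eye development each ommatidium — a cluster of
eight photoreceptors (R1–R8) plus accessory cells — rotates 90° relative to
the morphogenetic furrow while its combined apical surface constricts. The
cluster moves through a field of undifferentiated interommatidial cells
(ICs), whose motility, neighbor exchange, division and delamination set the
effective fluidity of the tissue the cluster must turn within. `ommatidyn`
implements the measurement side of such live-imaging experiments: it
consumes tracked, segmented label-image movies (plus FRAP and
laser-ablation traces) and quantifies

* cluster rotation `R(t)` (angle of the R2→R5 centroid line against the
  furrow axis) and apical area `A(t)` (sum over recruited R cells);
* logistic fits of both, with the rate conventions
  `Ω = 60·R₁/(4τ)` (°/h) and `C = 60·A₁/(4τ)` (µm²/h);
* pulse segmentation of `dR/dt`, constriction/expansion totals, and the
  rotation–constriction cross-correlation;
* IC event ledgers (divisions, delaminations, neighbor exchanges), 90-min
  binned statistics, trajectories relative to the cluster, and grid-averaged
  displacement fields;
* cell-shape (jamming) statistics built on the shape index `p₀ = L/√A`;
* FRAP recovery fits `I_N(t) = A(1−e^{−kt})` and ablation recoil fits
  `L(t) = l_f(1−e^{−t/T})`.

Because real tracked movies are large and third-party, the package ships a
synthetic-data module that generates movies, ledgers, and traces with known
ground truth; every measurement operation is validated against those
schedules in the test suite.

## Why the sigmoid is a logistic

The rotation and constriction rates are defined from fit parameters as the
amplitude divided by `4τ` and rescaled to hours. That identity —
`max slope = amplitude/(4τ)` — is specific to the three-parameter logistic
`R(t) = R₁/(1+e^{−(t−t₀)/τ})`; no other common sigmoid family (Gompertz,
error function) satisfies it with the same constant. The package therefore
fixes the family as the logistic, fitting

* rotation: `R(t) = R₁/(1+e^{−(t−t₀)/τ})` (3 parameters), and
* area: `A(t) = A₀ − A₁/(1+e^{−(t−t₀)/τ})` (4 parameters, baseline
  included),

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Initialization
is data-driven (amplitude from the data range, `t₀` from the mid-crossing,
`τ = span/8`), with box bounds `τ ∈ (0, 4·span]` and amplitudes in
`[0, 2·range]`. A `τ` pinned at its bound is flagged; a constant series is
refused (no inflection). On noiseless synthetic series the fits recover all
parameters to better than four significant figures.

`Ω` is computed from the *fitted* amplitude so the same code serves
under-rotating (low-fluidity) clusters whose amplitude is well below 90°;
`rate_nominal` additionally reports the conventional value computed with the
90° full turn, since the printed rate formula uses the literal 90.

## Wild-type parameters pinned by the printed numbers

The synthetic generator's wild-type defaults are obtained by inverting the
reported headline values rather than chosen freely:

| quantity | value | source of constraint |
|---|---|---|
| rotation amplitude `R₁` | 90° | full ommatidial turn |
| rotation `τ` | `60·90/(4·11)` ≈ 122.7 min | angular velocity 11 °/h |
| area baseline `A₀` | 20 µm² | plateau ≈ 8 µm² and ≈ 60% constriction |
| area amplitude `A₁` | 12 µm² | same two constraints solved jointly |
| area `τ` | `60·12/(4·2.5)` = 72 min | constriction rate 2.5 µm²/h |
| exchange schedule | 7 → 4 ICs/ommatidium/frame-pair, linear | reported decline over the imaging period |
| frame interval | 10 min | acquisition protocol |
| FRAP sampling | 20 s | acquisition protocol |
| recoil sampling | 2 s | kymograph calibration |

`t₀ = 250 min` places the inflection mid-way through a 500-min observation
window, matching the reported up-to-500-min tracking span; with these
values the apical area ends near 40% of its initial value, i.e. ≈ 60%
constriction.

The low-fluidity (LOF) and high-fluidity (GOF) presets are qualitative
transformations of wild type — ×0.3 and ×2.5 on IC motility and exchange
rates, reduced/increased pulse stabilization, under-/over-rotation — because
no numeric rates are published for them. They exist to give the pipeline a
strictly ordered fluidity series (`lof < wild_type < gof` in motility,
exchange, expansion totals, and mean shape index), which the tests assert at
fixed seeds.

## The kinematic phantom

The movie generator is deliberately kinematic, not mechanical: it does not
solve a vertex model, it renders prescribed schedules.

* The cluster occupies a disk of area `A*(t)`; R8 is a central disk
  (radius 0.4 of the cluster radius) and R1–R7 are seven annulus sectors
  whose boundaries rotate rigidly by `R*(t)`. Sector symmetry makes the
  R2→R5 centroid line track `R*(t)` exactly, so the rotation round trip is
  limited only by rasterization (< 0.5° at 0.1 µm/px).
* ICs are the nearest-seed (Voronoi) cells of points on a jittered
  hexagonal lattice performing seeded Gaussian random walks with per-frame
  step `ic_motility_um_per_frame`; seeds are kept out of the cluster
  footprint and inside the field.
* Rasterization is nearest-assignment at `pixel_size_um` (default
  0.05 µm/px, so geometric error is far below the 1°/2% round-trip
  tolerances; the test suite uses 0.1 µm/px, which is still comfortably
  sufficient, to stay fast).
* R7 recruitment is defined *on the constriction curve itself*: the first
  frame at which the noiseless `A*(t)` falls below 0.85 of its initial
  three-frame mean (R1/R6 at the 0.95 crossing). This mirrors how
  recruitment is estimated from data when R7 joined before acquisition, and
  it makes the `align_at_r7()` estimator testable against ground truth.

What the phantom does **not** emulate: point-spread blur, photobleaching of
the imaging channel, segmentation errors, curved or flowing fields, cell
packing mechanics, or forces. Passing round trips therefore certify the
*measurement* code — geometry extraction, tracking bookkeeping, fitting —
not robustness to segmentation noise in real movies.

## Pulses

Individual clusters rotate and constrict pulsatile: runs of positive
rotation rate alternate with anti-rotation. The paper-level description
gives no generative form, so the generator models the modulation as a
zero-mean rectified sinusoid, `a·(|sin(πt/P)| − 2/π)`, added to the
schedule, with period `P` (default 40 min) and amplitude `a` equal to
`pulse_amplitude` times the schedule amplitude (default 0.08). Scaling by
the schedule amplitude (rather than by the instantaneous rate) is what
makes the rate change sign between pulses — a rate-proportional modulation
below 100% can never produce the anti-rotation intervals that pulse
segmentation is supposed to find.

Segmentation computes `dR/dt` by centered differences, smooths with a
3-frame moving average (the smoothing used is not reported; 30 min is the
shortest centered window at the 10-min cadence), and splits the series into
maximal runs of positive smoothed rate ("pulse") and their complement
("anti"); the threshold is exactly zero, with no hysteresis. At 10-min
sampling a 40-min pulse period sits at the smoothing scale and neighboring
pulses can merge, so the pulse-count property (detected count within ±1 of
`duration/P`) is asserted at `P ≥ 80 min`, where the modulation is
resolvable; the 40-min default remains available for qualitative use.

## Geometry from label images

`build_cell_graph()` extracts, per cell: a sub-pixel boundary polygon
(marching-squares contour of the binary mask at level 0.5), area, perimeter,
centroid, neighbor set (shared pixel edges, 4-connectivity — corner contact
does not make neighbors), side count, and a border flag. Two numerical
choices matter:

* **Perimeter** is measured on a Douglas–Peucker simplification (tolerance
  0.8 px) of the contour. The raw marching-squares polyline overestimates
  the length of oblique straight edges by up to ~8% (staircase bias);
  simplification recovers straight cell–cell interfaces and brings the
  error against ground-truth polygons below ~2%.
* **Area** is measured on the *unsimplified* contour, which is accurate to
  < 0.5% regardless of edge orientation (simplification can shift area by
  up to the tolerance at each corner, which is the larger error).

Border-touching cells are flagged and excluded from shape statistics, since
their perimeter is truncated by the field of view.

The shape index `p₀ = L/√A` follows: scale-invariant, bounded below by the
isoperimetric value `2√π ≈ 3.545`, equal to `√(4n·tan(π/n))` for regular
n-gons, and equal to 3.81 for the regular pentagon — the proposed jamming
transition point. `field_shape_stats()` reports the mean and SD of `p₀`
over the first- and second-level IC neighbors of a cluster (first level =
adjacent to any R cell at the R7 frame, cone cells included by default with
an `exclude_cones` switch, since their membership in the published shape
statistics is not stated; second level = adjacent to first, minus cluster
and first level). Jamming classification is reported as a comparison
against 3.81, never baked into pass/fail logic.

## Event scoring

**Divisions** are scored where a track's lineage splits into exactly two
daughters appearing on the frame after the parent's last, with combined
first-frame area within [0.6, 1.4] of the parent's last area and the
daughters mutually adjacent. **Delaminations** are tracks that end before
the movie does, with no daughters, area decreasing monotonically over the
final three frames and collapsing below 25% of the track's median area (the
threshold is a tunable argument); tracks alive at the last frame are
censored, never scored.

**Neighbor exchange** needs a definition robust to concurrent events: a
first-level IC scores in frame pair (t, t+1) if its neighbor-id set changes
after (i) remapping daughters to their founder ancestor and (ii) deleting
ids absent from either frame. Rule (i) stops a neighbor's division from
scoring as an exchange; rule (ii) does the same for delaminations. The
synthetic event ledger plants exchanges as edge toggles — ring edges
between consecutive first-level cells (a symmetric swap scoring both
participants) plus single first-to-second-level toggles for odd targets —
so any scheduled per-pair count up to the 12 available first-level cells is
realized exactly, and detector recovery can be asserted with equality, not
tolerance. An exchange is attributed to every participating first-level
cell (both cells of a swap), matching counts phrased as "number of ICs
that underwent exchange".

Binned statistics use 90-min bins with mean ± SEM across ommatidia; with a
single ommatidium the SEM is reported as 0 and flagged rather than left
undefined.

**Displacement fields** follow the grid-average convention: trajectories
are expressed relative to the instantaneous cluster centroid over a 120-min
window after R7 recruitment; the plane is divided into 1.25-µm grid cells;
each occupied cell holds the average net displacement of the ICs that pass
through it, with speed interpolated bilinearly onto a 4× finer grid
(unoccupied cells are excluded from the interpolation support).

## FRAP and recoil

FRAP normalization follows
`I_N(t) = (I(t) − I_min)/(I_max − I_min)` after multiplying the ROI by the
bleach coefficient `mean_ref(t_first)/mean_ref(t)` computed from all
supplied reference junctions (their number and aggregation are not
specified upstream; the mean is the obvious robust choice). `I_max` is the
mean over all pre-bleach frames (robust to single-frame noise); `I_min` is
the single first post-bleach frame, per the "immediately after bleaching"
wording. The fit `I_N = A(1−e^{−kt})` reports the mobile fraction `A`, rate
`k`, recovery rate `A·k` (the slope at t = 0), and `T½ = ln 2/k`. Mobile
fractions slightly above 1 (≤ 1.2) are tolerated with a warning rather than
clipped, since normalization noise can push an essentially fully mobile
junction over 1. At the acquisition design used throughout (40 points,
20 s, noise SD 0.05 on `I_N`), the Cramér–Rao floor for `k` is ≈ 7%
relative; the test suite asserts < 2% bias and < 8% RMSE at exactly that
design.

Recoil fits use the normalized recoil `(l(t) − l₀)/l₀` and the rise
`L = l_f(1−e^{−t/T})`, reporting amplitude `l_f`, timescale `T`, and
initial speed `l_f/T`. High-fluidity tissue shows a qualitatively different
response — an initial opening followed by resorption of the gap — for which
the exponential is the wrong model; `fit_recoil()` screens for this
signature (median-smoothed recoil peaking and then dropping by more than
20% of the peak, threshold tunable) and returns `fit_ok = FALSE` instead of
a misleading fit. Flat traces yield a degenerate zero-amplitude result,
also flagged. The synthetic viscoelastic mode multiplies the elastic rise
by an `e^{−t/T_env}` envelope (default `T_env = 5T`) to produce exactly
this phenotype.

Adult-eye rotation angles are treated on [0°, 360°), so an over-rotation
peak near 270° is representable; distribution comparisons use the
two-sample Kolmogorov–Smirnov test and the two-tailed t test (Student by
default, Welch optional), wrapped from base R.

## Problem sizes and reproducibility

All simulations are sized so the full suite runs in well under a minute:
movie round trips use 12–26 frames at 0.1 µm/px in a 14-µm field, ledgers
use 34 frames (≈ 5.5 h), trajectory ensembles use 11 series of 51 points —
the same n as the published cluster ensemble. Generators are deterministic
given (preset, seed): identical inputs give bit-identical movies, ledgers
and traces. `scripts/acceptance.R` regenerates the headline quantities
(mean Ω, mean C, plateau area, pentagon p₀) from scratch at any seed.

## Known limitations

* The phantom's ICs are Voronoi cells of random walks; their shape-index
  distribution is realistic in ordering but not calibrated to measured
  eye-disc distributions.
* Pulse amplitude and period are placeholders (no quantitative values are
  published); only their qualitative consequences (sign-alternating rates,
  genotype-ordered expansion totals) are asserted.
* Exchange targets above the 12 first-level cells of the template graph are
  capped at 12 — a count of exchanging ICs cannot exceed the ICs present.
* `measure_area()` before full recruitment sums only the annotated subset
  of R cells; the round-trip tolerance is therefore stated on the aligned
  (post-R7) window.
* The recoil viscoelasticity screen is a heuristic on the trace shape; it
  flags, it does not classify mechanics.
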