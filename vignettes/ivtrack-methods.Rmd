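---
title: "Methods: track motility, behavioural quadrants, and collagen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: track motility, behavioural quadrants, and collagen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtrack)
```

`ivtrack` implements the downstream quantitative analysis of multiphoton
intravital imaging of migrating immune cells in skin. This vignette is the
package's own account of the models and conventions it uses, the parameters
that matter, and the choices made where the underlying methodology left the
design open.

## The data model

The atomic input is a **track**: one cell's time-ordered 3D positions, in
physical micrometres, at a nominally uniform frame interval (60 s by
default, over 30-min recordings — 31 frames). Tracks arrive as a long CSV
(`track_id, frame, t_s, x_um, y_um, z_um` plus optional `mouse`, `fov`,
`group` metadata) or as a per-track summary export of the style produced by
commercial tracking software. Validation requires strictly increasing
frames and times within a track, finite coordinates, and at least two
points. Missing frames are allowed and *recorded*, never interpolated: the
metrics layer bridges a gap with the single straight segment between the
flanking observations, which slightly underestimates path length but
fabricates no positions.

Two deliberate conventions at this layer:

* **Physical units only.** Coordinates are micrometres. The µm-per-pixel
  calibration of an acquisition cannot be assumed by software — it must be
  applied by whatever exports the tracks.
* **2D inputs are accepted** with `z = 0`; all geometry downstream is 3D
  and degrades gracefully.

## Per-track motility metrics

For positions $\mathbf{x}_1,\dots,\mathbf{x}_n$ at times $t_1,\dots,t_n$:
total track length $L$ (sum of step lengths), displacement $D$ (first to
last point), duration $T = (t_n - t_1)/60$ min, mean velocity
$\bar v = L/T$, confinement ratio $C = D/L$.

* *Mean velocity* is defined as path length over duration. This equals the
  mean of per-step speeds only when frame intervals are uniform; under
  gaps, the path-based definition remains meaningful, which is why it was
  chosen. Whether a given commercial package averages instantaneous speeds
  instead is generally undocumented; the definition used here is stated so
  results are comparable on their own terms.
* *Convention for immobile cells:* $L = 0$ makes $C = 0/0$; the package
  assigns $C = 0$. This is inconsequential downstream: such a cell has
  $\bar v = 0$ and is static under any velocity threshold.
* $C$ is clamped to $[0, 1]$ to absorb floating-point overshoot on exactly
  collinear tracks.
* Default filters reject tracks with fewer than 5 points or shorter than
  5 min — a guard against spurious short tracks dominating summaries. Both
  are configurable and the rejection log names every excluded track; oracle
  tests and simulations set them to 0.

## Behavioural quadrants

The $\bar v$-vs-$C$ plane is split at $\bar v = 2$ µm/min (about one cell
width of net motion per recording) and $C = 0.2$: Q1 static, Q2 slow but
directed ("intermittent migration"), Q3 fast and directed ("continuous
migration"), Q4 fast but confined. A cell is **motile** when
$\bar v \ge 2$ µm/min; the boundary is inclusive by that standard
definition, and the confinement boundary is made inclusive to match (only
the velocity inclusivity is conventionally stated).

One semantic tension is worth flagging rather than hiding: the quadrant
nomenclature pairs "intermittent migration" with *high* confinement ratio.
Since the confinement ratio measures straightness, this reads
counter-intuitively; it reflects that slow cells which do migrate tend to
do so in short directed bouts. The package follows the established quadrant
semantics as stated and does not reinterpret them.

Aggregation follows the experimental hierarchy exactly: quadrant
percentages are formed within each field of view, fov values are averaged
per mouse, and mouse values are averaged per group with SEM
$= \mathrm{SD}/\sqrt{n_\text{mice}}$. This keeps a mouse with many cells
from dominating its group. The pooled-over-cells motile fraction is also
exposed (it is the natural companion of cell-level velocity dot plots);
the hierarchical version is the default for bar summaries.

Cell density is the mean over sampled regions of count/volume, reported in
cells/mm³ ($1\,\mathrm{mm^3} = 10^9\,\mathrm{µm^3}$). Velocity histograms
use half-open bins $[kw, (k+1)w)$ with a default width of 0.5 µm/min —
fine enough to resolve the 2 µm/min line; published frequency curves rarely
state their binning, so the width is configurable.

## Collagen (SHG) quantification

Stacks are `(z, y, x)` arrays with physical voxel sizes and a surface
reference plane (default: the first acquired plane; automated surface
detection is out of scope). The standard measurement crops a follicle-free
150 × 150 µm lateral region (origin floored, extent rounded, in voxels),
extracts the xy plane at a depth below the surface
(index $=$ surface $+$ round(depth / z-step); 60 µm is the conventional
reporting depth) or a zx cross-section, and measures the percentage of
pixels **at or above** a threshold.

The threshold rule must be explicit for the measurement to be
reproducible, so the default is Otsu's method — maximizing between-class
variance on a 256-bin histogram — with a fixed-threshold override; the
value used is always recorded in the output. Two numerical details:

* On a cleanly bimodal image every cut through the empty inter-mode gap
  ties for maximal between-class variance; the package returns the
  midpoint of the tying range rather than an arbitrary edge of the gap.
* A constant image has no Otsu threshold; the intensity itself is returned
  with a warning (making the whole image "positive", which the warning
  makes visible).

Per-image Otsu is the default; when comparing timepoints, a global fixed
threshold removes the per-image adaptation and both modes are exposed for
that reason.

## The synthetic experiment generator

The generator exists so that every stage — I/O, metrics, classification,
aggregation, statistics, SHG — can be tested against known ground truth,
since raw intravital recordings are rarely shareable at test scale. It is
first-class, tested code, not a fixture.

**Tracks** are discrete-time persistent random walks with a two-state
pause/run Markov chain. In the run state the direction is the previous
direction blended with a fresh random unit vector by the persistence
weight and renormalized; the step length is
$\max(0, \mathcal N(\mu_s, \sigma_s))$ per minute scaled to the frame
interval. Phenotypes with a confinement radius are tethered to an anchor
(a hair-follicle proxy) by a harmonic pull subtracted each frame, with the
spring constant chosen so the stationary RMS distance from the anchor is
about a third of the radius — excursions beyond the radius are strongly
mean-reverting, which is what produces fast-but-confined (Q4) behaviour.
Localization jitter ($\mathcal N(0, \sigma_\text{noise})$ per coordinate)
is added to the *recorded* positions, and positions reflect at the volume
boundaries.

Default phenotypes (all with 0.2 µm localization jitter, chosen once as a
realistic sub-pixel tracking error):

| phenotype | speed (µm/min) | persistence | pause/resume | anchor | designed quadrant |
|---|---|---|---|---|---|
| static | 0 | — | always paused | — | Q1 |
| intermittent | 4 ± 1 | 0.6 | 0.5 / 0.3 | — | below 2 µm/min (Q2/Q1) |
| continuous | 4 ± 1 | 0.9 | never pauses | — | Q3 |
| fast_confined | 6 ± 1 | 0.5 | never pauses | 25 µm radius | Q4 |

The intermittent pause/resume rates give a stationary run fraction of
0.375, hence a mean velocity of about 1.5–1.8 µm/min including jitter —
below the motility line by design, though individual tracks straddle it
(over 30 frames the run-fraction variance is substantial, so roughly a
quarter of intermittent tracks land above 2 µm/min). The 25-µm anchor
radius sits well inside the ~50-µm follicle neighbourhoods within which
confined dermal T cells are typically observed to orbit. The default
lateral field is 300 × 300 µm — a realistic dermal field for a 25×
objective, chosen once as a generator property (no µm-per-pixel
calibration of any particular instrument is implied), with 100 µm imaging
depth and 2 µm z steps.

Because the intermittent phenotype straddles the threshold, the
mixture-recovery validation (a cohort with true motile weight 0.5, checked
against the exact binomial interval) is built from the two well-separated
phenotypes, static and continuous: that check is meant to measure
multinomial sampling recovery, and a binomial reference is only valid when
phenotype→motile classification is essentially deterministic. The
boundary behaviour of the intermittent phenotype is asserted separately
(majority below the line).

**Seed handling.** A single root seed spawns an independent stream per
track via counter-based splitting on the (group, mouse, fov, track)
indices (`seed_child()`), so enlarging a cohort never perturbs previously
generated tracks, and every output is a pure function of (config, seed).

**SHG stacks** are unions of random capsules (fibre segments, mostly
in-plane with a small tilt spread) rendered into a voxel grid until the
mask's volumetric fill is within half a percentage point of the target
(the stopping rule tolerates at most the 2-point band the generator
promises). Background noise is bounded above by a known ceiling (80) and
fibre signal bounded below (100), so a fixed threshold between the two
recovers the ground-truth mask exactly; Otsu must then also separate them.
What this generator does *not* emulate: PSF blur, depth-dependent
attenuation, photon noise, fibre bundling and anisotropy. Passing tests
therefore demonstrate the correctness of the measurement chain on images
whose answer is known — not robustness to real microscopy artefacts.

## Statistics

Two-group comparisons use the Mann-Whitney U test (midranks for ties).
The p-value is exact by full enumeration when the smaller sample has ≤ 8
observations and there are no ties — enumeration there costs at most a few
thousand splits — otherwise a normal approximation with tie-corrected
variance and continuity correction. Three or more groups use
Kruskal-Wallis with Dunn's post hoc (pooled-rank z statistics with
tie-corrected variance). Dunn raw p-values are adjusted by Holm-Šídák
step-down by default — the same family used for the per-quadrant
comparisons — with Bonferroni as an option. Quadrant bar summaries between
two groups are compared with one Welch t test per quadrant on mouse-level
percentages, Holm-Šídák-corrected across the four quadrants; Welch is
chosen over pooled-variance since equal variances cannot be assumed for
percentage data near the boundaries. Degenerate inputs (all values
identical) return p = 1 with a warning rather than NaN.

## Pipeline and reproducibility

`run()` composes the stages from one declarative config (R object or
YAML): ingest or simulate → metrics → classification and hierarchical
summaries → group statistics → SHG tasks → report. Config validation
collects *all* violations before any computation. A failing SHG task is
recorded in the report and does not abort the track analysis. Output
tables carry no timestamps (provenance, including a config hash and the
package version, lives in the JSON report), so synthetic-mode runs with
the same seed write byte-identical CSVs.

## Problem sizes used in validation

The test-suite and acceptance-script simulations are sized for a
laptop-scale run while keeping Monte-Carlo margins comfortable: 100 random
tracks for oracle agreement at $10^{-9}$ relative tolerance; 200 tracks
per phenotype for quadrant recovery; 200 cohorts of 200 tracks for
binomial-interval coverage; exhaustive Mann-Whitney enumeration up to
6 + 6; 2000 null replicates for type-I calibration; one 150 × 150 µm,
10-plane fibre stack at 85 % fill for the collagen chain.

## Known limitations

* Cell detection and linking are out of scope; tracks are taken as given.
* Gap bridging slightly underestimates path length (stated above).
* The confinement ratio conflates slow wandering with true confinement at
  short durations; the quadrant system inherits this, as flagged.
* Per-image Otsu adapts to each image's histogram; cross-timepoint
  comparisons that need a common scale should use a fixed threshold.
* The synthetic generator validates the analysis, not the microscope: its
  simplifications are listed above and its parameters are conditions of
  the simulated study, not fitted quantities.
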