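# ivtrack

Quantitative analysis of immune-cell interstitial migration from multiphoton
intravital microscopy (MP-IVM) of skin.

Time-lapse imaging of fluorescently labelled cells — for instance regulatory
T cells in the dermis — produces *tracks*: time-ordered 3D positions of each
cell across a 30-minute recording. `ivtrack` turns those tracks, plus the
accompanying second-harmonic-generation (SHG) collagen images, into the
standard quantitative readouts of such experiments, and ships a synthetic
experiment generator so every stage of the analysis can be validated against
known ground truth. It is aimed at imaging labs that track cells with
commercial software and want a scripted, reproducible, testable downstream
analysis.

## What it computes

For a track with positions $\mathbf{x}_1,\dots,\mathbf{x}_n$ at times
$t_1,\dots,t_n$:

- **total track length** $L=\sum_{i=2}^{n}\lVert\mathbf{x}_i-\mathbf{x}_{i-1}\rVert$ (µm),
- **displacement** $D=\lVert\mathbf{x}_n-\mathbf{x}_1\rVert$ (µm),
- **mean velocity** $\bar v = L/(t_n-t_1)$ (µm/min),
- **confinement ratio** $C=D/L\in[0,1]$ (1 = perfectly straight).

Each cell is then placed in one of four behavioural quadrants of the
$\bar v$-vs-$C$ plane using a migration-velocity threshold of 2 µm/min and a
confinement threshold of 0.2 (threshold values count as "high"): **Q1**
static, **Q2** intermittent migration (slow but directed), **Q3** continuous
migration (fast and directed), **Q4** fast but confined. A cell is *motile*
when $\bar v \ge 2$ µm/min. Quadrant percentages are aggregated
field-of-view → mouse → group (mean ± SEM over mice), and groups are
compared with Mann-Whitney, Kruskal-Wallis + Dunn's post hoc, or
Holm-Šídák-corrected Welch t tests, as appropriate. Cell density is
reported as cells/mm³. SHG stacks are cropped to a follicle-free
150 × 150 µm region, a plane is extracted (xy at a depth below the skin
surface, or a zx cross-section), and the percent area above an Otsu or
fixed intensity threshold is measured.

The synthetic generator simulates the same kind of experiment: cohorts of
persistent random walks drawn from a mixture of four behavioural phenotypes
(static / intermittent / continuous / fast-confined, the last tethered near
a follicle-like anchor), with the standard acquisition geometry (60-s frame
interval, 30-min recordings, 2-µm z steps), and fibrous collagen-like image
volumes with a known fill fraction.

## Worked example

Simulate a resting-skin group (8.5 % true motile weight) against an
inflamed group (60 % motile weight), then quantify and compare:

```r
library(ivtrack)

cfg <- synthetic_config(
  groups = list(
    untreated = c(static = 0.85, intermittent = 0.065, continuous = 0.05, fast_confined = 0.035),
    inflamed  = c(static = 0.2,  intermittent = 0.2,   continuous = 0.4,  fast_confined = 0.2)),
  n_tracks = 30, n_fov = 3, n_mice = 4, seed = 1)

tracks  <- simulate_cohort(cfg)
metrics <- classify_tracks(metrics_table(tracks, min_points = 0, min_duration = 0))
summarize_behaviour(metrics, level = "group")
#> # A tibble: 2 × 13
#>   group     mean_pct_Q1 sem_pct_Q1 mean_pct_Q2 sem_pct_Q2 mean_pct_Q3 sem_pct_Q3
#> 1 inflamed         18.3      0.556       14.7       2.58        48.9        2.31
#> 2 untreated        86.1      1.47         3.89      0.962        6.67       1.64
#>   mean_pct_Q4 sem_pct_Q4 mean_motile_pct sem_motile_pct n_mice n_tracks
#> 1       18.1       2.37             66.9           2.5       4      360
#> 2        3.33      0.454            10             1.50      4      360

mann_whitney(metrics$mean_velocity[metrics$group == "inflamed"],
             metrics$mean_velocity[metrics$group == "untreated"])
#> Mann-Whitney U (normal approximation, tie-corrected, continuity-corrected)
#> statistic = 110167, p = 1.97398e-59 (n = 360, 360)
```

The summary reads exactly like the quadrant bar charts of an imaging paper:
the inflamed group has ~67 % motile cells (Q3 + Q4, mean ± SEM over 4 mice)
against ~10 % in resting skin, and the velocity distributions separate at
vanishing p. The whole analysis can equally be driven from one declarative
YAML config via `run()` / `read_run_config()`, or from the shell with
`inst/scripts/ivtrack.R {validate|simulate|analyze}`.

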