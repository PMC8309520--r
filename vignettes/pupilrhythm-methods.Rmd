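---
title: "Measuring motion sickness from pupillary rhythms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motion sickness from pupillary rhythms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilrhythm)
library(dplyr)
```

## The measurement model

Motion sickness under a head-mounted display is treated here as a
high-cognitive-load state that leaves a physiological trace in the
dynamics of pupil size. Three assumptions carry the whole method:

1. the pupil can be localized in infrared images accurately enough that
   its diameter, in pixels, is a usable physiological signal;
2. collapsing the frame-rate diameter signal to a 1 Hz *pupillary
   rhythm* preserves the slow dynamics of interest while absorbing
   blinks and frame-level detection noise;
3. the sickness state expresses itself as a level shift (mPD), a
   dispersion increase (sPD), and a loss of spectral coherence (PRC
   ratio) of that rhythm.

The package does not attempt millimeter calibration: camera geometry is
unknown in the intended setting, so every size stays in pixels. All
comparisons (paired tests, covariate adjustment, classification) are
within-rig, where the unit cancels.

## Pupil detection

Each frame is binarized at a threshold linear in the frame's mean and
maximum brightness (`compute_threshold()`, coefficients −0.418, 1.051,
7.973). The coefficients were calibrated on an IR eye-imaging rig and
are exposed as a configurable parameter, since they cannot be expected
to transfer to a different camera unchanged.

Candidate pupil centers are seeded from the centroids of the largest
dark connected components of the binarized mask (default three), each
refined by the circular edge detector (`circular_edge_detect()`): the
objective is the Gaussian-smoothed (σ = 1.5 px) radial derivative of
the circle's normalized contour integral of intensity, with the contour
integral discretized as the mean of 64 bilinear samples and the radial
derivative as a central difference over r ± 1 px. The center search
runs on an integer grid (stride-2 coarse pass, ±1 px refinement) within
10 px of each candidate; the radius estimate is refined to sub-pixel
precision by a parabolic fit through the objective's peak. Pixel
coordinates are 0-based with integer pixel centers — the convention
every sub-pixel test in the suite pins against.

When several circular edges survive, the fit closest to the corneal
glint — the centroid of the largest connected region of near-saturated
pixels (≥ 250 gray; corneal reflections of an IR lamp saturate the
sensor) — is selected. A frame with no admissible fit (no dark
component of plausible area, or edge score below the floor of 2 gray
levels/px) yields no diameter at all: occluded frames are marked
invalid rather than imputed.

Two deliberate simplifications: the full circle is integrated (no
eyelid arc masking), and the reported diameter is `2r` from the
circle fit rather than an equivalent-area diameter from the mask — the
circle fit is the final localization step, so it is also the
measurement.

## From trace to indicators

`resample_rhythm()` reads "1 s window, 1 s resolution" as
non-overlapping block means — the only reading that actually produces a
1 Hz series. Within a window only valid samples are averaged, so a
blink shorter than a second costs nothing. A window with *no* valid
sample is filled by linear interpolation between neighboring defined
windows (edge windows take the nearest defined value); this goes beyond
the sub-second-blink rule, which is silent about longer gaps, and is
flagged by the `valid_fraction` column so downstream users can filter.

`rhythm_spectrum()` mean-subtracts the rhythm, applies a periodic
Hanning window, and keeps one-sided power in (0, 0.5] Hz. The DC bin is
excluded from both the dominant-peak search and the total power: with a
~35 px mean, including DC would make every PRC ratio vanish, which is
incompatible with the working range of the indicator (roughly 0.04–0.6).
The normalization is pinned by Parseval's identity — with a rectangular
window the retained power sums to `sum((x - mean(x))^2)` — and is
internal: only the PRC *ratio* is comparable across implementations,
not absolute power.

`prc_ratio()` defaults to a single-bin dominant band; the half-width is
configurable because "band" has no canonical width. A useful
consequence of the Hann window, verified in the tests: a noiseless
on-bin sinusoid yields a ratio of exactly 2 (amplitude leaks 0.5 / 0.25
/ 0.25 into three bins), so even a perfectly periodic rhythm does not
produce an unbounded ratio unless the band half-width is ≥ 1. The sPD
uses the sample (n − 1) standard deviation.

## SSQ scoring

The 16 symptoms and their overlapping factor memberships (7 per factor;
5 symptoms load on two factors) are serialized in `ssq_items()` so the
scoring is auditable, and the weighted total is
`(N·9.54 + O·7.58 + D·13.92) · 3.74`. Scores are linear and
item-monotone by construction.

## Statistics

`cohort_stats()` mirrors the within-subject study design: paired
t-tests (pre vs post, per condition) with Cohen's d computed as
`mean(diff)/sd(diff)` (sample sd); ANCOVA of post-viewing values
between conditions with the pre-viewing value as covariate, reporting
the group F with partial η² = SS_group/(SS_group + SS_residual); and
partial correlations of post-viewing SSQ with each indicator, computed
from the residuals after regressing both on their pre-viewing values.
All p-values are two-sided. The three pupillary indicators are flagged
at Bonferroni α = 0.05/3 ≈ 0.0167; the SSQ total at the family α.
Degrees of freedom are computed from the rows actually supplied (a
24-subject cohort gives paired dfs of 23); published analyses of this
design sometimes report larger dfs from pooling, which the package does
not replicate. A Shapiro–Wilk p-value for the paired differences is
reported as advisory only — the test is never switched automatically.

## Classification

One row per (subject, condition) post-viewing session, features
(mPD, sPD, PRC), HMD as positive class. "Box constraint" is the SVM
cost C (7.7 linear, 0.09 RBF); the RBF kernel scale defaults to
1/n_features on standardized features, exposed in the spec since it is
otherwise unstated. The decision tree uses the deviance (information)
split criterion, pruned to at most 4 splits. Standardization parameters
are always estimated on training rows only — inside each CV fold too —
and frozen into the model for held-out use. Cross-validation is
stratified and seeded; the reported confusion counts are *pooled*
across folds (a documented choice; per-fold averaging is the main
alternative), and the AUC comes from the pooled decision scores via a
hand-rolled trapezoidal ROC that the tests hold equal to Mann–Whitney
pair counting and to an independent ROC library.

## The synthetic-data generator

The generator defines the study conditions the package is tested
against. Frames: concentric pupil (gray 30) and iris (140) disks on a
sclera background (220) with a saturated glint and optional Gaussian
noise — intensity spacing chosen so the automatic threshold lands
between iris and sclera and the pupil/iris edge (110 gray) dominates
the iris/sclera edge (80), as in a well-exposed IR image where the
pupil is the strongest circular contrast. Traces: 5-min, 30 fps
sessions, `base + A·sin(2πft) + b(t)` with Poisson blinks marked
invalid. The broadband disturbance `b(t)` is white across seconds and
held constant within each second, i.e. band-limited to the analysed
0–0.5 Hz range: frame-rate white noise would be annihilated by the 1 s
averaging (÷√30), leaving the rhythm unrealistically clean, whereas
in-band noise survives it, which is exactly the irregularity the PRC
ratio is meant to detect.

Preset anchors: every non-sick session uses base 35 px, dominant
amplitude 1.3 px at 0.1 Hz, broadband sd 0.9 px, giving mPD ≈ 35 px,
sPD ≈ 1.3 px, PRC ≈ 0.5; post-HMD uses base 43 px, amplitude 0.3 px,
broadband sd 2.5 px, giving mPD ≈ 43, sPD ≈ 2.5, PRC ≈ 0.04. With the
Hann peak holding ~2/3 of the sinusoid's power, PRC ≈ 0.5 requires
noise variance ≈ sinusoid variance; amplitude 1.3 with sd 0.9 satisfies
both that and sPD ≈ 1.3 simultaneously, which fixed the preset. SSQ
items are Binomial(3, p) draws with condition-dependent rates
(0.015 pre, 0.03 post-2D, 0.12·severity post-HMD), ordering post-HMD ≫
post-2D ≫ pre. Cohorts add a per-subject baseline offset (sd 1.5 px)
and severity (mean 1, sd 0.3, floor 0.2) that drives both the pupil
effect and the SSQ rate, producing the positive/positive/negative
pattern of SSQ–indicator correlations; the `"null"` preset draws all
four sessions from the same regime, making labels exchangeable.

What passing on this generator does and does not show: it validates
the numerics (detection geometry, spectral normalization, statistics,
CV hygiene) and the qualitative signature, but real recordings bring
eyelid occlusion of the pupil boundary, gaze-dependent foreshortening,
luminance responses, non-sinusoidal rhythms and 1/f-like backgrounds
that the generator deliberately omits. Accuracy on the synthetic
cohorts should be read as a ceiling, not a forecast.

## Numerical and scale choices

Degenerate inputs: constant rhythms have zero spectral power — the PRC
is reported as `NA` rather than fabricated; a spectrum with essentially
all power in the dominant band returns `Inf` with a warning. Zero
difference variance rejects the paired t; constant inputs reject the
partial correlation; a baseline collinear with the group factor rejects
the ANCOVA. Ties in the edge-score and ROC sweeps break deterministically
(first maximum; simultaneous ROC steps).

Problem sizes in the test suite are chosen to keep the full run in a
few minutes on one core: detection tests use 160×120–200×150 px frames
(the CDE objective is resolution-independent at these scales),
cohort-level checks use 24 subjects at 60–300 s sessions over a handful
of seeds, and the frames-to-decision check renders 40 s sessions at
5 fps (the frame count, not the method, is the cost driver). The
acceptance script regenerates a full 24-subject, 5-min-session cohort
plus a 23-subject held-out cohort at every invocation.

## Known limitations

No eyelid/eyelash modeling or arc masking; no ellipse fit (strong gaze
angles violate the circle model); threshold coefficients are
rig-specific; absolute spectral power is implementation-internal; the
online decision uses a 60 s rolling window by default, a deliberate
departure from the 5-min offline window in favor of responsiveness,
with the window length exposed in `pipeline_config()`.
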