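# pupilrhythm

Non-contact measurement of motion sickness from pupillary rhythms.

Head-mounted-display (HMD) virtual reality frequently induces motion
sickness, but the standard instruments for detecting it are either
subjective questionnaires or body-contact sensors (EEG, ECG) that are
awkward under a headset. `pupilrhythm` implements an alternative: the
pupil is imaged by an infrared camera, its diameter is tracked frame by
frame, and motion sickness is read out of the *rhythm* of the diameter
signal. The package is aimed at researchers in visual ergonomics,
VR human factors and pupillometry who want a fully scripted, testable
version of this pipeline, exercisable end-to-end on synthetic data.

## The method

1. **Pupil segmentation.** Each grayscale IR frame is binarized with an
   automatic threshold that is linear in the frame's brightness
   statistics,

   `T = -0.418 * B_mean + 1.051 * B_max + 7.973`,

   and the pupil boundary is localized by a Daugman-style circular edge
   detector: maximize over center and radius the Gaussian-smoothed
   radial derivative of the normalized contour integral of intensity,

   `max_{r, x0, y0} | G_sigma(r) * d/dr  (1 / 2*pi*r) ∮ I(x, y) ds |`.

   When several circular edges compete, the one closest to the corneal
   glint (the saturated reflection of the IR lamp) is taken.

2. **Pupillary rhythm.** The 30 fps diameter signal is collapsed to
   1 Hz by non-overlapping 1 s block means; blinks shorter than 1 s are
   absorbed by the averaging, and diameters are simply not computed
   while the pupil is occluded.

3. **Indicators.** From the rhythm: `mPD` (mean diameter, px), `sPD`
   (sample SD, px), and the **pupillary rhythm coherence ratio**
   computed from the Hanning-windowed FFT power in 0–0.5 Hz:

   `PRC = P_dominant_band / (P_total - P_dominant_band)`.

   Motion sickness shows as mPD↑, sPD↑, PRC↓ — a larger, more
   irregular, spectrally dispersed rhythm.

4. **Ground truth and decision.** The 16-item Simulator Sickness
   Questionnaire is scored as
   `total = (N*9.54 + O*7.58 + D*13.92) * 3.74`; cohorts are analyzed
   with paired t-tests (Cohen's d), baseline-covariate ANCOVA (partial
   η²), partial correlations and Bonferroni correction (α = 0.05/3);
   and LDA / decision-tree / linear-SVM / RBF-SVM classifiers (box
   constraints 7.7 and 0.09) are evaluated by stratified 10-fold CV and
   held-out testing with accuracy, sensitivity, specificity and AUC.

A synthetic-data module renders ground-truth IR eye frames (dark pupil,
iris, sclera, saturated glint), simulates diameter traces with
condition-dependent rhythm structure and blink gaps, and builds labeled
within-subject cohorts, so every stage is testable without recordings.

## Worked example

```r
library(pupilrhythm)

# a 5-min post-HMD session and its three indicators
tr <- simulate_trace("postHMD", duration = 300, seed = 42)
features_from_trace(tr)
#>     mPD   sPD    prc
#> 1  42.8  2.71 0.0324

# a 24-subject within-subject cohort; paired pre/post tests in HMD
co  <- simulate_cohort(24, "strong", seed = 42)
rep <- cohort_stats(co)
tidy(rep) |> dplyr::filter(condition == "HMD", analysis == "paired_t")
#>   indicator statistic  p_value effect significant
#> 1 mPD           15.5  1.20e-13   3.16 TRUE
#> 2 sPD           12.6  8.45e-12   2.57 TRUE
#> 3 prc          -30.3  4.99e-20  -6.18 TRUE
#> 4 ssq_total      8.68 1.02e- 8   1.77 TRUE

# RBF-SVM, 10-fold cross-validation on the 48 post-viewing sessions
post <- dplyr::filter(co, phase == "post")
glance(crossval_classifier(post, classifier_spec("svm_rbf"), seed = 42))
#>   classifier split     n accuracy sensitivity specificity   auc
#> 1 svm_rbf    cv       48    0.979       0.958           1     1

# detection on a noisy synthetic frame recovers the generated pupil
fr <- render_eye_frame(width = 200, height = 150,
                       pupil_center = c(100, 75), pupil_radius = 20,
                       noise_sd = 8, seed = 1)
detect_pupil(fr, cde_params(10, 35))
#>     x0    y0     r diameter edge_score valid
#> 1  100    75  20.0     40.0       26.0 TRUE
```

The paired t rows say the HMD condition raised the mean and SD of the
rhythm and collapsed its spectral coherence, each with a very large
effect size; the classifier separates post-HMD from post-2D sessions
almost perfectly on this cleanly separated synthetic cohort.

A thin command-line front end over the same functions is installed at
`inst/cli/pupilrhythm.R` (subcommands `simulate`, `detect`, `features`,
`ssq`, `train`, `eval`, `stats`, `run`).

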