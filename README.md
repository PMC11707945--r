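# gajunct

**Junctional-zone microperimetry analysis for geographic atrophy, with an
inter-grader repeatability battery and a fully synthetic test bench.**

## What this is for

Geographic atrophy (GA) lesions enlarge while visual acuity often stands
still, so functional monitoring needs a measure tied to the lesion itself.
Microperimetry (MP) measures retinal sensitivity (dB) at 68 fixed loci of a
fovea-centered 10-2 grid; the informative stimuli are those in the
**junctional zone** — within ±250 µm of the GA margin traced on fundus
autofluorescence (FAF). Getting there requires registering the MP exam (on
its SLO fundus image) into the FAF frame from manually picked vessel-
bifurcation landmarks, which makes the analysis operator-dependent. This
package implements the whole pipeline and quantifies exactly how
operator-dependent it is:

* **Registration** — least-squares similarity transform (translation,
  rotation, isotropic scale; reflections disallowed) from ≥ 3 fiducial
  pairs, closed-form Procrustes solution with residual diagnostics.
* **Geometry** — traced GA foci as simple polygons (µm), 0.05 mm² minimum
  lesion filter, exact signed Euclidean stimulus-to-margin distance
  (negative inside atrophy), even-odd containment for multifocal tracings.
* **Zone metrics** — mean sensitivity and scotomatous-point count
  (raw −1 dB not-seen value or sensitivity < 0 dB) within the junctional
  (±250 µm) or perilesional (0–500 µm) zone.
* **Repeatability statistics** — Bland–Altman bias and 95% limits of
  agreement with individual CIs on each limit; ICC(A,1) (two-way random
  effects, absolute agreement, single measurement); coefficient of
  repeatability 1.96·√2·s_w (both conventions reported); a
  repeated-measures Bland–Altman via one-way variance components for
  stimulus-level data clustered by eye.
* **Synthetic studies** — multifocal star-convex lesions (~6.5 mm² expected
  area), a logistic distance-dependent sensitivity field, a simulated 4-2
  staircase with a psychometric observer, and grader-specific fiducial
  jitter — all deterministic under a fixed seed, with ground truth
  retained.

## Worked example

```r
library(gajunct)

# a 6-eye synthetic study: lesions, exams, two graders' fiducials
study <- simulate_study(sim_config(n_eyes = 6, seed = 11))

# one eye, one grader: register, distances, junctional-zone metrics
eye <- study$eyes[[1]]
analyze_exam(eye$exam, eye$tracing, eye$fiducials[[1]], study$config$faf_frame)
#> eye analysis: eye 1, grader grader1 (fit RMSE 1.57 px)
#> zone metrics: eye 1, junctional zone [-250, 250] um
#>   n in zone: 15, mean sensitivity: 9.93 dB (floor_zero), scotomatous: 1

# the full two-grader agreement battery
grader_agreement(study)
#> inter-grader agreement, junctional zone [-250, 250] um (sentinel: floor_zero, 291 um/deg)
#>
#> -- mean zone sensitivity (per eye) --
#> repeatability report (n = 6, units: dB)
#> Bland-Altman (n = 6): bias -0.07787, LOA [-1.199, 1.043]
#>   95% CI lower LOA [-2.29, -0.1077], upper LOA [-0.04803, 2.134]
#>   100.0% of units within the limits
#>   ICC [two-way random effects, absolute agreement, single measurement (ICC(A,1))]: 0.9274
#>   CoR (ANOVA, 1.96*sqrt(2)*s_w): 1.121; CoR (1.96*SD of differences): 1.121
#> ...
#> -- stimulus coordinate difference: 20.82 +/- 10.8 um (pooled over stimuli) --
```

Reading this: the 15 stimuli of eye 1 that fall within ±250 µm of its
lesion margin average 9.93 dB under grader 1's registration (not-seen
stimuli entering the mean as 0 dB — the convention is printed). Across the
six eyes, the two simulated graders' mean junctional sensitivities differ
by −0.08 dB on average with limits of agreement of about ±1.1 dB, an
ICC of 0.93, and the pair of transforms displace the same stimulus by
~21 µm on average — small against the 500 µm zone width.

A command-line wrapper covering the same workflow
(`grid`, `simulate`, `register`, `analyze`, `repeatability`) is installed
at `inst/cli/gajunct`:

```sh
Rscript inst/cli/gajunct simulate --n-eyes 6 --seed 11 --out study_dir
Rscript inst/cli/gajunct repeatability --study study_dir
```

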