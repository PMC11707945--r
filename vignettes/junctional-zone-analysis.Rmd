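---
title: "Junctional-zone microperimetry analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junctional-zone microperimetry analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gajunct)
```

## The problem

Geographic atrophy (GA), the late stage of non-exudative age-related macular
degeneration, produces sharply demarcated atrophic lesions that enlarge over
time. Visual acuity is a poor monitor of that enlargement: large extrafoveal
growth can leave acuity untouched. Microperimetry (MP) measures light
sensitivity (in dB of stimulus attenuation) at fixed, fundus-tracked retinal
loci and can, in principle, detect the functional decline that accompanies
lesion growth — but a whole-grid summary dilutes the signal, because most
stimuli of a standard grid lie either deep inside the atrophy (already at
floor) or far outside it (unaffected). The quantity of interest is therefore
sensitivity restricted to the *junctional zone*: the band of retina within
250 µm of the GA margin on either side, where change is expected first.

Relating MP stimuli to the lesion margin requires registering the MP exam
(acquired on a scanning-laser-ophthalmoscopy image, SLO) into the frame of
the fundus-autofluorescence image (FAF) on which the lesion was traced. That
registration is the operator-dependent step: two graders picking vessel
bifurcation landmarks will produce slightly different transforms, hence
slightly different stimulus-to-margin distances, zone memberships, and zone
metrics. This package implements the full analysis pipeline **and** the
statistical battery for quantifying how repeatable it is between graders —
together with a synthetic-study generator with known ground truth, so that
every stage is testable without any patient data.

## The pipeline

For one eye the analysis proceeds as:

1. **Registration.** Each grader supplies ≥ 3 corresponding landmark pairs
   (SLO pixels → FAF pixels). The similarity transform (translation,
   rotation, isotropic scale — no shear, no reflection) minimizing the sum
   of squared target-frame residuals is obtained by the closed-form
   orthogonal-Procrustes-with-scale solution on centroid-centered point
   sets. Three or more non-collinear pairs identify the four parameters with
   residual degrees of freedom to spare; collinearity is detected from the
   singular values of the centered source configuration (ratio below
   `1e-6`). If the data favor a reflection, the best proper-rotation
   solution is returned and a diagnostic is set — a fundus image cannot be a
   mirror image of another fundus image, so a reflective fit indicates a
   data error. All pairs are weighted equally, matching a workflow where a
   grader picks a few curated points.

2. **Coordinate chain.** Stimulus centers are defined on a fovea-centered
   grid in visual degrees, mapped to SLO pixels (fovea at frame center),
   through the fitted transform to FAF pixels, and scaled to micrometers on
   the retina. Stimuli are treated as 2-D points (the Goldmann III diameter,
   0.43°, is carried as metadata only).

3. **Signed distance.** The lesion tracing is a set of simple polygons in
   FAF micrometers. After applying the 0.05 mm² minimum-lesion-size filter,
   the signed Euclidean distance from each stimulus to the nearest point on
   any retained focus boundary is computed exactly (point-to-segment minima
   over all edges); the sign is negative inside the atrophy, positive
   outside, with containment decided by the even-odd rule so that nested
   tracings (islands of spared retina) behave sensibly. A stimulus exactly
   on the margin gets distance 0 with non-negative sign.

4. **Zone metrics.** A zone is an inclusive band on the signed distance:
   junctional `[-250, +250]` µm, perilesional `[0, +500]` µm. Per eye the
   package reports the number of stimuli in the zone, their mean
   sensitivity, and the number of scotomatous points (raw not-seen flag or
   sensitivity < 0 dB; the inequality is strict at 0).

5. **Agreement battery.** With two graders analyzing the same exams and
   tracings, the package compares: eye-level mean zone sensitivity,
   eye-level scotomatous counts, stimulus-level signed margin distances
   (all 68 per eye, eye as cluster), and the per-stimulus Euclidean
   distance between the two graders' transformed coordinates.

## Coordinate and unit conventions

Pixel coordinates are 0-based, x rightward, y downward, origin at the
top-left pixel corner; fovea-centered degree coordinates are x rightward, y
**up**ward (so degree→image conversions flip the y sign); micrometer frame
coordinates share the pixel orientation. One fixed convention, applied
everywhere, avoids silent sign flips; all distances are Euclidean, so the
flip never affects magnitudes.

The degree→micrometer scale is not a device constant and is not derivable
from frame metadata alone. The package uses a configurable `um_per_degree`
with default **291 µm/°** (the emmetropic schematic-eye convention) and
surfaces it in every report, so results can be rescaled for other
assumptions. With the default 30° × 30° / 768 × 768 FAF frame this gives
30/768 × 291 ≈ 11.37 µm per pixel. Only square fields are supported;
anisotropic metadata is rejected rather than half-supported.

## The 10-2 grid

The rectilinear 10-2 pattern is generated as the lattice of odd-integer
degree coordinates (x, y ∈ {±1, ±3, ±5, ±7, ±9}) retained when
x² + y² ≤ 82. This is the unique symmetric radius cutoff on the 2°-spaced
odd lattice that yields the standard 68 points (17 per quadrant): 82 keeps
(±9, ±1) and drops (±9, ±3) at 90. The device's native stimulus ordering is
not public, so a deterministic row-major order (top-left to bottom-right) is
imposed and documented; all cross-grader correspondence is by `stimulus_id`,
never by nearest-neighbor matching, because both graders transform the same
acquisition.

Sensitivities live on the device scale [0, 36] dB with −1 as the not-seen
sentinel. How a sentinel enters the *mean* is genuinely ambiguous — −1 is
not a measured threshold — so the averaging convention is an explicit
parameter: `floor_zero` (default; the sentinel counts as 0 dB),
`as_recorded` (−1 enters the mean), or `exclude` (not-seen stimuli are
dropped from the mean but never from the scotomatous count). The convention
used is recorded in every result; none is claimed to be "the" field
standard.

## The agreement statistics

Let $d_i$ be the grader-1 − grader-2 difference for unit $i$ (eye or
stimulus), $n$ the number of units.

**Bland–Altman.** Bias $\bar d$; limits of agreement
$\bar d \pm 1.96\,s_d$. The multiplier is fixed at 1.96 (the usual "± 1.96
SD" convention); Student-$t$ enters only the confidence intervals on the
limits, whose half-width is
$t_{0.975,\,n-1}\; s_d \sqrt{1/n + 1.96^2/(2(n-1))}$.

**ICC.** The intraclass correlation is computed in the two-way
random-effects, absolute-agreement, single-measurement form (ICC(A,1)):
with units-by-raters mean squares $MS_R$, $MS_C$, $MS_E$ and $k = 2$ raters,
$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$
"ICC" without a form label is ambiguous; absolute agreement is the
defensible choice when the question is whether graders are interchangeable,
and the form label is printed in every report. When the total variance is
zero the ICC is undefined and reported as `NA` with a warning — never
silently as 0 or 1.

**Coefficient of repeatability (smallest real difference).** Primary form
$\mathrm{CoR} = 1.96\sqrt{2}\,s_w$, with $s_w^2$ the within-unit
(between-grader) error variance, i.e. the residual mean square of the same
two-way ANOVA. The literature also uses $1.96\,s_d$; both are reported. For
the two-rater two-way design the two coincide algebraically
($MS_E = s_d^2/2$ exactly, because the rater main effect absorbs the bias),
which the report makes visible rather than hiding — with more raters, or a
one-way decomposition, they would differ.

**Repeated measures.** Stimulus-level differences (68 per eye) are not
independent: a registration error shifts a whole eye coherently. The
differences are modeled as $d_{ij} = \mu + a_i + e_{ij}$ with a random eye
intercept; $\sigma_a^2$ and $\sigma_e^2$ are estimated by the one-way ANOVA
method of moments (negative moment estimates truncated at zero) and the
limits of agreement are $\mu \pm 1.96\sqrt{\sigma_a^2 + \sigma_e^2}$. For
the balanced two-grader design the moment estimator coincides with REML
whenever the estimate is interior (the suite verifies this against `lme4`),
and the closed form is exactly testable. With one observation per cluster
the components are not separable and the plain Bland–Altman is returned;
a single cluster falls back likewise, with a warning.

## The synthetic-study generator

No study data are distributable, so the generator is a first-class module
whose defaults encode a realistic 30-eye GA cohort:

* **Lesions.** 1–3 star-convex foci per eye. Each focus has a radial
  profile $r(\theta) = R\,(1 + \rho\, g(\theta))$, where $g$ is a smooth
  zero-mean periodic harmonic mixture (orders 2–5) normalized to unit RMS
  and $\rho = 0.15$; star-convexity keeps every polygon simple by
  construction. Base radii are log-normal (sdlog 0.3) around a median of
  1300 µm, scaled by $1/\sqrt{n_\text{foci}}$ so the expected *total*
  lesion area — $\pi R^2 e^{2\sigma^2}(1+\rho^2) \approx 6.5$ mm² — does
  not depend on focality, matching the cohort scale the method is aimed at.
  Foci are placed disjointly around the fovea (center offsets N(0, 600 µm),
  widening if placement retries accumulate). Holes are not generated;
  multifocality is modeled by disjoint foci, though the analysis side
  handles nesting via the even-odd rule.

* **Sensitivity field.** True thresholds follow a logistic ramp in the
  signed margin distance: −5 dB deep inside (below the device floor, i.e. a
  dense scotoma), 28 dB far outside, transition half-width 125 µm. The
  −5 dB inside level is what makes not-seen outcomes and scotomatous counts
  appear organically.

* **Measurement.** Optionally, each stimulus is measured by a simulated 4-2
  staircase on the [0, 36] dB scale: start at 25 dB, 4 dB steps (dimmer
  after seen, brighter after not seen) until the first response reversal,
  2 dB steps until the second; the estimate is the last-seen level, and a
  miss at 0 dB (the brightest stimulus) terminates with the −1 sentinel.
  The true device protocol is proprietary; this two-reversal variant is a
  documented stand-in, not claimed device-exact. The observer answers
  "seen" with probability $\Phi(\text{slope} \cdot (T - L))$; slope = ∞
  gives the deterministic observer, for which estimates are within 2 dB of
  the truth across [2, 34] dB (verified exhaustively). With the staircase
  off, the exam is the clamped true field and the whole pipeline is an
  exact function of ground truth.

* **Graders.** Grader $j$ picks $\max(3, \text{round}(N(\mu_j, \sigma_j)))$
  fiducials, with $(\mu, \sigma)$ defaults (3.3, 0.7) and (4.6, 1.7);
  source points are spread over the central SLO frame with a minimum
  pairwise separation (which also guarantees non-collinearity), mapped
  through the eye's true transform, and jittered isotropically at **both**
  ends (both images are viewed by the grader), default SD 1 px — a
  realistic click precision for vessel bifurcations. Unit noise is always
  drawn and then scaled by the SD, so runs with the same seed and different
  jitter levels share the same noise realization (common random numbers);
  this makes degradation curves across jitter levels smooth and
  monotonicity properties testable without enormous replication.

Under a fixed seed the generator is fully deterministic, byte-identical on
disk across reruns.

### What the generator does and does not emulate

It reproduces the *structure* of a grader-repeatability study: shared exams
and tracings, grader-specific registration error, distance-coupled
sensitivity, device-style censoring at the floor. It does not emulate FAF or
SLO pixel content, fixation instability, tracing variability (tracings are
inputs, held fixed, exactly as in the workflow the package implements), eye
movement artifacts, or non-similarity deformation between SLO and FAF — the
latter being, in practice, a dominant source of real inter-grader
discrepancy. Passing tests therefore certify the analysis machinery and the
statistics, not the field performance of human graders.

## Numerical choices and degenerate inputs

* Zone bounds are inclusive at both ends; distance 0 (on the margin) counts
  as outside the atrophy but inside both zone kinds.
* Distances are computed to filtered foci only (the 0.05 mm² filter runs
  first, mirroring the tracing protocol order); a tracing left empty by the
  filter raises an explicit no-lesion error for the caller to handle.
* An empty zone yields `NA` metrics with an `empty_zone` flag — undefined,
  never silently zero.
* Polygons are normalized counterclockwise on construction; self-
  intersecting or zero-area outlines are rejected at the door, by exact
  sign tests on edge pairs with no tolerance.
* The similarity fit centers both point sets at their centroids before the
  SVD; exact-recovery on consistent pairs holds to 1e-9 and is enforced in
  the suite over 1000 random transforms.
* Signed distances agree with a brute-force oracle (0.1 µm boundary
  sampling plus winding-number containment) to better than 0.5 µm over
  1000 random multifocal instances.

## Problem sizes in the test suite

The suite runs 30-eye studies for the jitter degradation curve (four jitter
levels), 1000-case oracle sweeps for registration and distance geometry,
and n = 3000 simulations for the ICC/CoR consistency checks; the whole
suite completes in well under a minute on a single core, and the
`scripts/acceptance.R` report (a fresh 30-eye study plus the full battery)
runs in a few seconds. These sizes were chosen as the smallest that pin
each estimator's error well below its assertion tolerance.

## Known limitations

* The similarity class cannot represent true SLO↔FAF deformation; the
  package deliberately mirrors that limitation rather than correcting it.
* The 291 µm/° default ignores axial-length individual variation; all
  µm-valued outputs inherit that assumption (and state it).
* Scotomatous counts in simulated cohorts are small integers with limited
  between-eye variance, so their ICC is noisier than the sensitivity ICC —
  visible in the acceptance report.
* The staircase stand-in and the device's true algorithm may differ in
  start level, reversal rules and tie handling; only the documented variant
  is simulated.
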