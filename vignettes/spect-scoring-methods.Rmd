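---
title: "Automated SPECT scoring and prognosis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated SPECT scoring and prognosis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectscore)
```

# Overview

`spectscore` quantifies myocardial SPECT studies in three stages —
circumferential profiles, polar map, 17-segment scores — and couples the
result to the survival statistics used for risk stratification in coronary
artery disease. This vignette is the package's own account of the methods:
what is assumed, which conventions are fixed, which parameters matter, and
where genuinely open design choices were resolved.

# Imaging model

## Input contract

A `short_axis_volume` is a 3D count grid already reoriented to the short
axis, slice 1 most apical, with at least 5 slices. Automatic reorientation
from transaxial data is deliberately out of scope: it is scanner-specific,
and keeping it out makes the quantification core testable in isolation.
Counts must be finite and non-negative; the tracer label
(`TL_STRESS`, `TL_REST`, `BMIPP`) travels with the volume.

## Circumferential profiles

For each slice and each of `n_angles` angular bins (default 60, minimum
12), the profile value is the **maximal count along the ray** from the
slice's myocardial centre outward. All short-axis slices participate — not
just three representative ones — which is the point of automated
quantification. Rays are sampled every half in-plane voxel with bilinear
interpolation, so profile values are sub-voxel accurate; on noise-free
annulus phantoms they agree with a 10-times-denser ray-marching oracle to
within one count unit.

The slice centre starts at the count-weighted centroid and is refined by
three ring-fitting iterations: along each ray the wall radius is taken as
the weighted mean position of the samples at or above half the ray's
maximum, and the centre moves to the unweighted mean of the wall points.
The refinement is essential with severe defects: a plain count-weighted
centroid is dragged several millimetres away from a severe defect, which
tilts every ray and smears the defect border into neighbouring segments
(enough to turn an absent-uptake segment's score from 4 into 3). The
half-maximum weighted radius, rather than the argmax sample, keeps the fit
smooth in the counts and invariant to count rescaling.

The **angular convention** is fixed and documented: bin 1 is centred on the
anterior wall and bins proceed counterclockwise as seen from the apex —
anterior, septal, inferior, lateral — matching the standard polar display.

An all-zero slice yields an all-zero profile and is flagged; an all-zero
volume is an error.

## Polar map and normalization

Slice profiles are resampled onto `n_rings` rings (default 36) by linear
interpolation along the long axis, apex innermost. The innermost ring is
the apical cap and carries the mean of the most apical slice's profile;
with no separate apical acquisition there is no angular information at the
true apex, so a constant cap is the honest choice. The default 36 × 60
geometry is deliberately finer than the 17-segment partition it feeds.

Percent uptake divides every bin by the **single maximal bin** and
multiplies by 100, so the maximum is exactly 100 and the normalizing count
is recorded. A percentile reference (e.g. the 99th) is exposed for
robustness against isolated hot pixels but is off by default, keeping the
literal maximal-data-point definition. Because the reference is a ratio,
percent uptake is invariant to global count rescaling — bit-identical for
lossless (power-of-two) scalings, and to floating-point precision
otherwise, since an arbitrary scale factor already rounds the input counts
themselves.

# Segmentation and scoring

## 17-segment mask

The mask partitions the ring × sector grid into the standard 17-segment LV
model: after reserving the innermost `ceiling(n_rings / 9)` rings for the
apex (segment 17), the remaining rings split into thirds by floor division
with the remainder given to the basal zone — outer third 6 basal segments
(60° each), middle third 6 mid segments, inner third 4 apical segments
(90° each). Numbering runs 1 basal anterior … 6 basal anterolateral,
7–12 mid, 13–16 apical anterior/septal/inferior/lateral, 17 apex.

`n_sectors` must be divisible by 6 and by 4. The apical 90° boundaries
(45° off the anterior axis) can then still fall inside a bin (e.g. with 60
sectors of 6°); bins are therefore assigned by their **centre angle** with
half-open arcs, which guarantees an exact partition — every bin in exactly
one segment, all 17 segments non-empty — for every supported geometry.
This is verified property-style across geometries in the test suite.

## Scores

Each segment's mean % uptake is expressed relative to that segment's
normal-database mean (× 100, capped at 100) and banded by four strictly
decreasing boundaries, default **70 / 50 / 30 / 10** % — the conventional
5-point bands; the published description of the original system defers its
exact thresholds to earlier technical work, so here they are declared
defaults, fully configurable via `threshold_table()` and the config file,
not a claim about the original calibration. The score is the number of
boundaries strictly above the relative uptake, so a segment exactly on a
boundary takes the milder score. The tie direction is arbitrary but must
be fixed for exact tests; inclusive-downward is documented here and
asserted in the suite.

The package **averages the segment first, then scores**; scoring each bin
and averaging afterwards would be a different (non-integer) statistic. The
shipped default normal database is uniform (mean 100 everywhere), which
reduces scoring to absolute uptake bands; `build_normal_db()` constructs a
population database (per-segment mean and SD) from defect-free phantoms,
and refuses degenerate populations with zero SD.

Summed scores are plain sums over the 17 segments (0–68). SDS clamps
per-segment negative differences to zero, so SDS ≥ 0 always and
SDS = SSS − SRS exactly when no segment scores worse at rest than at
stress. A summed score ≥ 4 is abnormal; ≤ 3 normal. The cutoff is
configurable but defaults to the established threshold.

# Synthetic data

## Phantom

The phantom is a half-ellipsoid myocardial shell: at long-axis fraction
$u$ (0 = apex), the mid-wall radius is $R\sqrt{1-(1-u)^2}$ with a Gaussian
transmural count profile (SD 6 mm) around it. Defaults — 12 slices of
8 mm, 64 × 64 in-plane at 2 mm, basal mid-wall radius 28 mm, peak 1000
counts — were chosen once as a plausible adult LV at SPECT-like resolution;
the 2 mm in-plane grid keeps bilinear sampling error of the wall peak
below ~1 % uptake so that pipeline accuracy, not phantom discretization,
limits the end-to-end checks.

Defects are defined in polar coordinates (centre angle, angular width,
fractional long-axis span, severity = remaining fraction of uptake), not
voxel lists, so the ground-truth polar map is computable analytically:
each bin's relative uptake is the product of severities covering its
(angle, long-axis) position, resampled to rings exactly as the pipeline
resamples slices and normalized to 100. The truth never touches the voxel
grid, making it an independent reference: on noise-free phantoms, measured
segment means agree with it within 2 % uptake. One caveat is inherent: a
perfectly sharp defect border is ill-conditioned for any finite sampling —
a bin whose centre ray runs exactly along the discontinuity can
legitimately land anywhere between the two plateaus. Defects therefore
accept an optional raised-cosine angular transition (`edge_deg`); the 2 %
end-to-end agreement is asserted for defect-free and smooth-edged
phantoms, while sharp edges remain the default for severity/extent and
score tests, where only plateau behaviour matters.

Poisson noise, when enabled, is applied last under the phantom's own seed;
an identical phantom description and seed give bit-identical volumes.

## Cohort simulator

`simulate_cohort()` draws covariates (diabetes, sex, age, LVEF, treatment
flags), per-segment stress scores from a categorical distribution, rest
scores by binomial thinning of stress (so no segment reverses and
SDS = SSS − SRS holds in simulated data), and BMIPP scores that copy the
stress segment with probability `bmipp_corr` (default 0.6) or redraw
independently — independent channels with configurable correlation, not a
biological discordance model. Event times are exponential with rate
$\lambda_0 \exp(\beta^\top x)$, administratively censored; given an event
it is hard with probability 0.25, echoing the roughly one-quarter hard
fraction typical of such cohorts.

The default preset emulates the structure of a 151-patient
suspected/known-CAD cohort without prior infarction: diabetes prevalence
14 %, LVEF 69 ± 8 %, age 65 ± 10, true hazard ratios 6.1 for diabetes and
1.18 per SSS point, administrative censoring at 2500 days, baseline hazard
3 × 10⁻⁵ /day chosen once to give roughly a 19 % marginal event rate under
those effects. These are *qualitative* settings: the simulator reproduces
the statistical structure such a cohort is assumed to have (and that the
estimators are validated against), never any particular dataset's numbers.

What passing tests show, and what they do not: the generators exercise the
estimators under exactly the model the analysis assumes (proportional
hazards, exponential baseline, independent censoring, cleanly shaped LV,
no attenuation/scatter or gating artefacts). Agreement there validates the
implementation, not the clinical performance of the scoring system on real
images or real outcome data.

# Prognostic statistics

Contingency tables take abnormal score as the positive and cardiac events
as the outcome; predictive values are reported unrounded and rounded to
integer percent, and an empty denominator yields an explicitly undefined
(`NA`) value, never zero. AND/OR flag combination builds the combined
tables.

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package — the
standard tool a practitioner would use — behind the package's interface;
ROC AUC and the DeLong paired comparison are delegated to `pROC`. The test
suite cross-checks each against independent hand computations (risk-set
product-limit, observed-minus-expected log-rank, exhaustive pair-counting
AUC), keeping a dual route between implementation and oracle. Cox fits use
the Efron tie approximation (accurate with the heavy day-level ties that
administrative follow-up produces; the original analyses' software does
not document its method). Hazard-ratio CIs are Wald. The global χ² is the
likelihood ratio against the null model, and the added value of a score is
its increment between nested fits, referred to χ² with df = number of
added covariates. No multiple-testing correction is applied anywhere,
matching the analysis style this mirrors.

Two censoring policies for the hard-event analysis are implemented because
the source material leaves the rule unstated: `censor` (default) censors
soft-event patients at their event time; `exclude` drops them. Neither is
claimed to be the original authors' rule. One terminal event per patient
is assumed. Follow-up is kept in days internally (with 30.44 days/month
for display conversions only).

Degenerate inputs fail loudly and specifically: constant or collinear
covariates, zero events, single-class ROC labels, single-patient baseline
groups, non-nested model pairs. A zero-event cohort still yields KM output
while the Cox/ROC step is refused with a recorded message.

# Problem sizes and reproducibility

The suite and the acceptance script were sized to run comfortably on a
single CPU: phantoms at the default 12 × 64 × 64 grid (~0.3 s through the
pipeline), Cox recovery at 100 replicate cohorts of n = 2000 (a few
seconds total), oracle comparisons on ≤ 200-point fixtures. All generators
are deterministic under their seed; CLI outputs carry the tool version, a
config hash and the seed in a header comment, so any table can be
regenerated from config + seed alone.

# Known limitations

- No attenuation or scatter correction, gating, or LVEF computation from
  images (LVEF is an external covariate); no DICOM networking or GUI.
- No automatic reorientation: input must already be short-axis.
- The normal database ships as a uniform default; a real low-likelihood
  population database must be built by the user (or from phantoms).
- Defect ground truth is analytic only because defects live in polar
  coordinates; voxel-painted pathologies would need a different reference.
- Visual/semi-quantitative expert scoring, vessel-territory sub-scores and
  defect extent in % LV are out of scope.
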