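# spectscore

Automated polar-map scoring and prognostic analysis of myocardial SPECT.

`spectscore` turns short-axis myocardial SPECT count volumes — stress/rest
thallium-201 perfusion and rest ¹²³I-BMIPP fatty-acid metabolism studies —
into quantitative risk markers, and provides the survival statistics used to
evaluate them in coronary-artery-disease cohorts. It is aimed at nuclear
cardiology researchers who want a fully scripted, reproducible alternative
to expert visual scoring.

## What it computes

**Imaging.** Every short-axis slice contributes a maximal-count
circumferential profile: for each angular bin, the maximal count along the
ray from the slice's myocardial centre (count-weighted centroid refined by
ring fitting). Profiles are resampled onto a ring × sector polar map (apex
at the centre, base at the rim; default 36 × 60) and normalized to percent
uptake relative to the single maximal bin, so the map maximum is exactly
100 %.

**Scoring.** The polar map is partitioned into the standard 17-segment left
ventricular model (6 basal + 6 mid + 4 apical segments + apex). Each
segment's mean % uptake, expressed relative to a normal-database mean, is
banded into a score

    s_i = #{ b in {70, 50, 30, 10} : b > u_i }  ∈ {0, …, 4}

(0 = normal, 4 = absent uptake; uptake equal to a boundary takes the milder
score). Summed scores follow the usual definitions over the 17 segments:

- SSS = Σ sᵢ on stress thallium, SRS on rest thallium, SBS on rest BMIPP
- SDS = Σ max(sᵢ_stress − sᵢ_rest, 0)
- a summed score ≥ 4 is abnormal; ≤ 3 is normal.

**Prognosis.** 2×2 contingency tables of abnormal score against cardiac
events (all or hard-only) with positive/negative predictive values and
AND/OR score combination; Kaplan–Meier event-free curves with log-rank
tests; Cox proportional-hazards fits (Efron ties) with Wald 95 % CIs and
global χ² increments for nested models; ROC AUC with DeLong comparison of
correlated curves; baseline group-comparison tables (Welch t /
Pearson χ²).

**Synthetic data.** A digital LV phantom (half-ellipsoid shell, Gaussian
transmural profile, polar-coordinate defects, Poisson noise) with analytic
ground-truth segment uptake, and a cohort simulator with
proportional-hazards event times — so the whole pipeline is testable
without patient data.

## Worked example

```r
library(spectscore)

# phantom with one severe defect (5% residual uptake) covering the
# mid-anterior segment
spec <- phantom_spec(defects = list(
  list(center_deg = 0, width_deg = 72, span = c(0.33, 0.78), severity = 0.05)))
ph <- make_phantom(spec)

polar  <- volume_to_polar(ph$volume)       # profiles -> polar map -> % uptake
mask   <- build_segment_mask()             # 17-segment partition, 36 x 60
scores <- score_segments(polar, mask, "TL_STRESS")
scores
#> <segment_scores> TL_STRESS: sum 4 | 0 0 0 0 0 0 4 0 0 0 0 0 0 0 0 0 0
summed_score(scores)                       # SSS = 4
classify_abnormal(summed_score(scores))    # TRUE (>= 4 cutoff)
```

Segment 7 (mid anterior) scores 4 — absent uptake — and no other segment is
affected, so SSS = 4, which crosses the abnormality cutoff. On the cohort
side:

```r
co <- simulate_cohort(cohort_spec(seed = 42))  # 151 patients, paper-like mix
predictive_value_table(co)                     # 8 rows: SSS/SBS/AND/OR x ALL/HARD
cox_fit(co, c("dm", "sss"), "ALL")
#> <survival_fit> 30 events; global chi-square 23.59 (p = 7.55e-06)
#>  term   hr ci_lower ci_upper        p
#>    dm 4.34     2.05     9.18 0.000122
#>   sss 1.32     1.14     1.52 0.000151
```

Here diabetes and SSS per point both carry independent hazard, as the
simulation's generating model intends (true HRs 6.1 and 1.18).

A command-line wrapper (`inst/cli/spectscore.R`) exposes the same pipeline
as subcommands `score`, `polarmap`, `prognosis`, `phantom`, `cohort-sim`
and `normaldb-build`:

```sh
Rscript inst/cli/spectscore.R phantom --out ph.nii.gz --seed 3
Rscript inst/cli/spectscore.R score --out results ph.nii.gz
```

## Further reading

The methods vignette (`vignettes/spect-scoring-methods.Rmd`) documents the
model assumptions, the polar-map and segmentation conventions, the
synthetic-data generators and the numerical design choices in detail.
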