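# stilflow

Stromal tumor-infiltrating lymphocytes (sTIL) — mononuclear immune cells
within the cancer stroma of breast tumors — are scored by pathologists as
the percentage of stromal area they occupy, and the score predicts
response to neoadjuvant chemotherapy in HER2-positive and triple-negative
disease. Visual estimation is noisy: inter-observer differences of ten
percentage points or more are routine. `stilflow` is an R package for the
full quantitative workflow around an automated sTIL reader:

- **Scoring.** An automated reader detects lymphoid cells as points and
  segments cancer stroma as a mask, so the score is a normalized count:

  sTIL = α · (lymphoid count in stroma) / (stroma area / U),

  with U = 400 µm². Because lymphocytes are near-spheres of radius 3 µm,
  the exact geometric coverage multiplier is 100·π·9/400 = 7.068; the
  constant α is selected from candidates {6.5, 7.0, 7.5} by calibrating
  grid-level scores against a pathologist panel with Lin's concordance
  correlation coefficient (CCC).
- **Synthetic data.** Tissue-label rasters, doubly stochastic
  (log-Gaussian Cox) lymphoid point patterns with tunable spatial
  heterogeneity, biased/noisy visual raters, and an automated reader with
  imperfect lymphocyte recall and a stroma mask degraded to a target IoU.
- **Agreement statistics.** Lin's CCC with Fisher-z confidence intervals,
  per-case coefficient of variation, nonparametric Bland–Altman limits
  (2.5/97.5 percentiles), exact and continuity-corrected McNemar tests,
  and pooled/paired t comparisons.
- **Triage and revision.** The ten-percentage-point concordant/discordant
  rule, per-rater revisit flags against the automated score, a simulated
  assisted re-read, and full revisited-vs-rescored accounting with
  before/after discordance.
- **Response prediction.** Miller–Payne dichotomization (grades 4–5 =
  responder), sTIL strata (<10 / 10–49 / ≥50), and binary logistic
  regression fit from first principles by IRLS with Wald odds-ratio
  intervals, overall and by molecular subtype.

## Worked example

```r
library(stilflow)

map   <- generate_tissue_map(1024, 1024, mpp = 2, stroma_fraction = 0.4,
                             cancer_fraction = 0.35, seed = 7)
cells <- generate_cells(map, intensity_config(base_density = 8000,
                                              heterogeneity = 1.2), seed = 8)
true_stil(map, cells)$true_stil        # 22.99  (% geometric coverage)
score_slide(cells, map)                # sTIL 22.77% (3411 lymphoid cells
                                       #   in 0.419 mm^2 stroma)
dl <- simulate_dl_reader(map, cells, seed = 9)
dl$score                               # 16.50  (imperfect recall + mask)
dl$realized_iou                        # 0.666  (stroma IoU at target)
simulate_rater(map, cells, default_rater_profiles()$A, seed = 10)  # 20

simulate_grid_calibration(seed = 1)
#> alpha calibration on 249 grids
#>   alpha 6.5: CCC 0.6790 (overall), NA (<20)
#>   alpha 7.0: CCC 0.8657 (overall), NA (<20)
#>   alpha 7.5: CCC 0.7738 (overall), NA (<20)
#>   selected alpha: 7.0
```

The geometric truth (22.99%) and the α = 7 score (22.77%) differ by the
constant factor 7.0/7.068; the automated read is lower because a fifth of
lymphocytes are missed and the degraded mask drops cells near its
boundary. The calibration selects 7.0 because it is the candidate whose
scale best matches unbiased raters.

A full synthetic reader study — four raters, one automated reader,
triage, assisted revision, response analysis — runs in under a minute:

```r
st <- run_full_study(default_study_config(n_slides = 203, seed = 1))
print(st)
#> synthetic sTIL reader study: 203 slides, 4 raters + DL
#>   initial discordant: 119 (58.6%)
#>   after revision:     96 (47.3%), McNemar p = 2.3e-05
#>   COV 0.461 +/- 0.418 -> 0.386 +/- 0.415
#>   standalone CCC on concordant subset: 0.820
write_report_bundle(st, "stil_out")    # JSON report + CSV panels/cohort
```

Assisted revision reduces discordance and per-case dispersion and raises
every pairwise CCC; the responder group's mean sTIL exceeds the
non-responders', with monotone stratum odds ratios. A thin CLI over the
same functions lives at `inst/cli/stil-study.R`
(`run-all` / `simulate` / `score` subcommands, `--config --seed --out`).

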