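---
title: "Methods: sTIL scoring, reader agreement, and assisted revision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sTIL scoring, reader agreement, and assisted revision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stilflow)
```

## The problem

Stromal tumor-infiltrating lymphocytes (sTIL) — the mononuclear immune
cells sitting in the cancer stroma of a breast tumor — are scored by
pathologists as the percentage of stromal area they occupy. The score
predicts response to neoadjuvant chemotherapy in HER2-positive and
triple-negative disease, but visual estimation over a whole slide is hard
and inter-observer variation is notoriously large. An automated reader
that detects lymphoid cells as points and segments cancer stroma as a
mask can produce a reproducible score, and — more usefully — can act as a
reference against which each pathologist's estimate is triaged and, when
far off, revisited.

`stilflow` implements that whole workflow on synthetic data: a generator
for tissue maps, spatially heterogeneous lymphoid point patterns,
simulated raters and an imperfect automated reader; the normalized sTIL
score and its constant calibration; the agreement statistics; the
ten-percentage-point triage and revision machinery with full accounting;
and the response-prediction analysis.

## The score and its constant

An automated reader reports lymphoid cells as dots, not areas, so the
count per unit stroma area must be converted to an occupied-area
percentage:

$$\mathrm{sTIL} \;=\; \frac{\alpha \cdot \#\{\text{lymphoid in stroma}\}}
{\text{stroma area}/U}.$$

Lymphocytes are morphologically regular — roughly spheres of radius
3 µm, hence cross-section $\pi\,3^2 \approx 28.3$ µm². With the area unit
fixed at $U = 400$ µm², the exact geometric coverage multiplier is
$100\,\pi\,9/400 = 7.068$, which is why integer-ish constants near 7 are
the natural candidates. The constant is nevertheless treated as a
calibration parameter: `calibrate_alpha()` scores a panel of randomly
cropped grid patches under each candidate $\alpha \in \{6.5, 7.0, 7.5\}$
and selects the one whose raw (unclamped) scores maximize Lin's
concordance correlation coefficient against the rater-panel mean, with
ties broken toward the better low-range (panel mean < 20) CCC and then
the smaller constant. On unbiased raters the selection lands on 7.0
essentially always, because 7.0/7.068 is the scale factor closest to 1.

The choice $U = 400$ µm² is this package's convention; the score is
linear in the count and reciprocal in the area, and pooling any partition
of a slide (summing counts and areas) reproduces the slide score exactly.
Scores are clamped to $[0, 100]$ for reporting; calibration always sees
raw values.

## What the generator emulates

**Tissue maps.** A smooth Gaussian random field is thresholded by rank so
the highest values become cancer area and the adjacent band cancer
stroma: contiguous tumor nests ringed by stroma, with label fractions
exact to one pixel. Rasters default to 2 µm/px; coordinates are microns,
origin top-left, y downward, and a point maps to pixel
`floor(coord/mpp) + 1`. The native scale of a deployed system is not
being reproduced — only the geometry of the computation.

**Lymphoid patterns.** A doubly stochastic (log-Gaussian Cox style)
process: white noise smoothed at `field_correlation_length`,
exponentiated with gain `heterogeneity`, normalized to preserve the mean
density over stroma, then per-pixel Poisson counts. This is exactly an
inhomogeneous Poisson process thinned against the same piecewise-constant
field, vectorized. `heterogeneity = 0` recovers a homogeneous Poisson
process; larger values concentrate the same expected count into patches,
which is precisely the failure mode that makes visual field sampling
noisy. Cohort-scale slide-to-slide variation comes from drawing each
slide's target sTIL from a Beta distribution with mean 22.7% and SD
19.3% (a published reader-study cohort scale) and converting it to a
density via the 3-µm geometry (≈ 354 cells/mm² per sTIL point).

**Raters.** A rater samples `k_fields` windows centered on random stroma
pixels, computes the geometric coverage in each, multiplies by mean-one
lognormal noise (`meanlog = -sd²/2`, so "unbiased" means unbiased in
expectation), averages, applies a multiplicative then an additive bias,
rounds to a 5-point grain and clamps last. The four default profiles
(A–D) differ in bias direction, noise and revision behavior: one
systematic under-scorer with high revision compliance, two over-scorers,
one near-unbiased conservative reader. With zero noise, zero bias, grain
1 and a field covering the slide, the rater returns the true sTIL
rounded — the identity every test of the error model starts from.

**The automated reader.** True lymphoid cells are kept with probability
`lymphoid_recall` (default 0.79); spurious detections are added at
`false_positive_rate` per mm² of stroma (default 1300, which makes
precision comparable to recall at the cohort-mean density of about
8000 cells/mm², putting lymphocyte F1 near 0.79); and the stroma mask is
degraded by swapping equal numbers of pixels out of and into the mask,
chosen by a smooth random field so errors form blobs. Swapping a
fraction $a$ of the stroma pixel count in each direction yields IoU
$(1-a)/(1+a)$ exactly, so $a$ is solved from the target (default 0.666,
the deployed-model stroma IoU scale) and the realized IoU is within
rounding of the target; an unattainable target warns and reports the
realized value. Because the swap preserves the stroma pixel count, the
reader's bias comes from lost counts (imperfect recall, cells falling
off the displaced mask), mirroring the real system's tendency to read
low.

**What passing tests do not show.** The generator has no H&E appearance,
no nuclear morphology, no staining or scanner variation, no necrosis or
artifact regions, and rater error is stationary across slides. Agreement
statistics behaving correctly here says the machinery is right, not that
any particular clinical concordance level will be reproduced on real
slides.

## Triage, revision, accounting

A slide is *discordant* when the maximum pairwise difference among its
human scores reaches 10 points; a (slide, rater) pair is *revisited*
when |rater − automated| reaches 10. The boundary is inclusive by
default (a difference of exactly 10 triggers) and configurable, since
descriptions of such rules vary between "less than 10 means concordant"
and "more than 10 triggers". On revision the rater rescores with
probability `revision_prob` to
`round((1−w)·old + w·automated + ε)`, clamped; `w` is the rater's
reliance weight, and ε defaults to 0 (a deterministic pull; Gaussian
noise of a couple of points produces realistic partial-change rates).
The optional distrust branch (a rater moving away from a visibly wrong
automated read) is not implemented as a default behavior; its effect —
entries that are revisited but not rescored — is already produced by
`revision_prob < 1`.

Accounting distinguishes *revisited* from *rescored*, reports per-rater
rates over each rater's evaluated slides, unique revisited slides with
multiplicity strata (the union count always equals the strata sum), and
before/after discordance with an exact-or-corrected McNemar test on the
paired status changes (exact binomial below 25 informative pairs,
continuity-corrected chi-squared above).

## Statistics

- **Lin's CCC** uses biased (divide-by-*n*) moments — the original
  definition; with /(n−1) moments the three-point worked example would
  give 0.667 instead of 0.571. The 95% CI uses the Fisher z-transform
  with Lin's asymptotic variance; the source analysis did not state its
  CI method, so the standard asymptotic choice is used.
- **Bland–Altman** limits are nonparametric: the 2.5th/97.5th
  percentiles of the differences by linear interpolation between order
  statistics (the `h = (n−1)p + 1` convention, R's quantile type 7).
- **McNemar** switches from the exact two-sided binomial to the
  continuity-corrected chi-squared at `b + c = 25`.
- **Mean comparisons** go through `stats::t.test` (pooled-variance
  Student's t, or paired t), with zero-variance inputs raised as classed
  degenerate errors rather than silent NaNs.
- **Logistic regression** is fit by IRLS with Wald standard errors from
  the inverse observed information; the log-likelihood trace is
  monotone, convergence is a `1e-8` max coefficient change, and
  coefficients passing |β| > 30 raise a separation error with
  diagnostics. For a single binary covariate the fit reproduces the
  2×2 closed form `ad/bc` with `SE = sqrt(1/a+1/b+1/c+1/d)` to 1e-6.
  `stats::glm` serves as an independent oracle in the tests, never as
  the implementation.

## The response cohort

Subtypes default to 148 HER2-positive and 55 TNBC. The latent response
propensity is `beta0 + beta_stil·sTIL/10 + beta_subtype·1[TNBC]` plus
standard-logistic noise; Miller–Payne grades 1–5 are cut from the latent
variable at `(-2.2, -1, 0, 1.4)` and responders are grades 4–5. Fixing
the third cutpoint at 0 makes the dichotomization coincide exactly with
the logistic model, so refits recover `beta_stil` with nominal CI
coverage. Defaults `beta0 = -0.95`, `beta_stil = 0.3`,
`beta_subtype = 0.2` put the responder fraction near 45% at the cohort
mean sTIL, with responders scoring visibly higher — the regime the
analysis functions are meant to operate in. sTIL strata follow the
standard cuts: low < 10, intermediate 10–49, high ≥ 50 (the 10–49
definition of the intermediate band is used where sources disagree with
a 1–49 variant). Printed odds ratios from any particular clinical
cohort are not targets here: the strata contrasts are standard category
indicators against the low stratum.

## Problem sizes and numerical choices

The default full study uses 203 slides of 1.02 × 1.02 mm at 2 µm/px with
four raters and one automated reader; it runs in well under a minute and
exhibits the qualitative behavior of interest (discordance falls,
per-case COV falls, every pairwise CCC rises after revision, responder
sTIL exceeds non-responder sTIL, stratum odds ratios are monotone in
dose). Calibration replicates crop 249 grids of 1024 px from four
1280-px slides; 100 replicates complete in a few minutes. Monte-Carlo
tests (Poisson moments, thinning expectations, coverage simulations) use
fixed seed sets sized so their tolerance bands are multiple standard
errors wide. Degenerate inputs — empty stroma, constant panels, zero
variances, rank-deficient designs, out-of-range grades, illegal raster
codes — raise classed errors (`undefined_score`, `degenerate_stat`,
`invalid_config`, `separation_error`, `parse_error`, `invalid_record`)
so callers can distinguish them; empty-vs-empty detection F1 is defined
as 1 by convention.

## Known limitations

Grid crops within one slide share the slide's intensity field and
therefore correlate; the calibration's selection criterion (a scale
comparison) is insensitive to this, but grid-level CCC values should not
be read as independent-sample estimates. The automated reader's false
positives are uniform over the degraded stroma rather than clustered
near real cells. Rater profiles are time-invariant: no learning, fatigue
or washout effects. The Fisher-z CI for CCC is asymptotic and can be
anticonservative below a few dozen pairs.
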