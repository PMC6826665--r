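---
title: "Area-based DAB quantification and myoepithelial cell statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-based DAB quantification and myoepithelial cell statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcarea)
```

## The problem

In mammary carcinomas, the myoepithelial (ME) cell layer that surrounds
normal tubuloalveolar structures is gradually lost as in situ carcinoma
progresses to invasive disease, and partial myoepithelial differentiation
of the tumor cells themselves (detected by calponin immunostaining) is a
candidate prognostic feature. Quantifying these phenomena from
immunohistochemistry (IHC) requires two measurements per tumor:

1. **How much of the epithelial tumor area stains** for a marker
   (cytokeratin, smooth muscle actin, vimentin, calponin), split by
   staining intensity (weak / moderate / strong), from brightfield RGB
   images of DAB-stained sections; and
2. **Which cells stain**: percentages of spindle-shaped non-neoplastic
   ME cells (SME), hypertrophic (cuboidal-to-polygonal) non-neoplastic
   ME cells (HME), and neoplastic cells with myoepithelial
   differentiation (NME) among marker-positive cells.

These measurements are then correlated with signalment (age, sex) and
histology (tubular growth percentage, mitotic count per 10 high-power
fields, Elston–Ellis grading score) across a tumor cohort.

`ihcarea` implements this entire pipeline, together with a synthetic-data
module that generates both cohorts and image tiles with exact ground
truth, so every stage is testable without access to any slide archive.

## Stain quantification model

### Optical density and color deconvolution

Transmitted-light absorbance follows Beer–Lambert: per channel
$OD_c = -\log_{10}(I_c / I_0)$ with $I_0 = 255$ for 8-bit images, and the
OD vector of a pixel is (approximately) a nonnegative combination of the
stains' reference OD vectors. `separate_stains()` projects each pixel's
OD vector onto the standard published hematoxylin/DAB unit vectors
(`hdab_stain_vectors()`), solving the 3×3 linear system whose third axis
is the residual direction orthogonal to both stains. The DAB coordinate
is the per-pixel DAB optical density; negative loadings (deconvolution
residue) are clamped to zero. Pixels of pure counterstain therefore map
to DAB OD 0 and never count as positive.

### Illumination correction

`correct_illumination()` removes smooth multiplicative shading
(vignetting, lamp drift) before deconvolution. The field is estimated
from the *bright-quantile surface*: the tile is partitioned into ~8 px
blocks, the 90th intensity percentile per block — which tracks the
brightest, least-absorbing pixels, whose true intensity is nearly
constant — is taken per channel, and a degree-2 polynomial is fitted to
the block log-values. The exponentiated surface, normalized to mean 1,
is divided out. A pixel-wise fit was rejected during design: with
strongly bimodal stain content even a low-order surface fitted to all
pixels absorbs a percent-level amount of tissue structure, while the
block-quantile statistic has within-class variance of only a few gray
levels. Degenerate tiles (essentially saturated, black, or constant) are
flagged and passed through unchanged.

### Intensity classes and area readout

`classify_pixels()` labels each analyzed pixel by half-open DAB-OD
intervals $[0,t_1)$, $[t_1,t_2)$, $[t_2,t_3)$, $[t_3,\infty)$ — a
boundary pixel takes the upper class, so ties are deterministic. The
default thresholds $(0.15, 0.40, 0.80)$ are configuration, not
constants: on real material they must be calibrated per staining batch;
here they are chosen so the synthetic generator's class bands straddle
them (below). `quantify_areas()` then reports each class as a percent of
the analyzed area; the denominator is the full analysis mask (the whole
tile by default, with an optional luminance-based `tissue_mask()` for
fields containing glass). The four class percentages sum to 100 exactly
and the total positive area is the weak + moderate + strong sum.

One caveat this package makes explicit: in the original web-application
readout that inspired this design, the printed class percentages (44.86
+ 20.76 + 15.83 = 81.45) do not sum to the printed total stained area
(88.45). Whether a fourth unreported bin or a typo is responsible is
undecidable from the publication; `ihcarea` enforces exact additivity,
so its total is always the sum of its parts.

## Area-based scores

From an area profile with weak/moderate/strong percentages $W, M, S$:

$$\mathrm{IRS}^{area} = \frac{W + 5M + 10S}{100} \in [0, 10], \qquad
\mathrm{H}^{area} = W + 2M + 3S \in [0, 300].$$

The IRS formula is printed ambiguously in the source material (the
bracketing could be read as dividing only the strong term by 100); the
whole-sum reading is implemented because only it yields the 0–10 range
consistent with the published score tables (cytokeratin maximum 5.35,
median 2.06). Both scores are linear in $(W, M, S)$, so the score of the
mean field profile equals the mean of per-field scores —
`summarize_marker()` may therefore average 1–3 fields per tumor in
either order. Scores are kept at full precision; rounding is a
presentation concern.

## Cell metrics

`aggregate_cell_percentages()` converts a per-cell annotation table (one
row per marker-positive cell, with category SME/HME/NME and intensity
mild/moderate/marked) into per-tumor percentages. The pipeline's primary
input is an annotation table rather than a detector output, because cell
counting in this setting is a manual task; `classify_cell_shape()` (a
spindle-vs-polygonal dichotomy at major/minor axis ratio ≥ 2.5, a
configurable cutoff) is provided for synthetic end-to-end tests only.
SMA and vimentin label only non-neoplastic ME cells, so NME records for
those markers are rejected, and for two-category markers the SME and
HME percentages are complementary. "Hypertrophic" is treated purely as
a morphological label; no size threshold is applied.
`grade_from_score()` maps grading scores 3–5, 6–7, 8–9 to grades I, II,
III.

## The synthetic cohort

`generate_cohort()` emulates a case series of 119 rabbit mammary
carcinomas. Marginals (all configurable via `cohort_params()`):

* **Age**: truncated normal, mean 5.3 y, SD 1.59 y on [1.5, 10]; 22 of
  119 missing. Truncation shifts the realized mean/SD to ≈5.33/1.53.
* **Sex**: 79% female vs female-spayed among 107 known; 12 missing.
  Counts are composition-exact because sex carries no planted
  correlation.
* **Tubular growth**: scaled beta with an interior mode on [5, 90]%.
* **Mitotic count**: negative binomial (size 1.6, mean 7), truncated to
  [0, 32] — right-skewed, as mitotic counts are.
* **Grading score**: the printed study distribution 2/13/42/21/21/2 %
  over scores 3–8, renormalized (it sums to 101% as printed).
* **Immunopositive areas**: per-marker scaled betas matched exactly
  (by root-finding on the beta quantile function) to the published
  range and median of each marker; markers share a tumor-level latent
  factor (correlation 0.5). The weak/moderate/strong split is a shared
  Dirichlet draw with concentration (9.3, 5.0, 0.75), chosen once so
  that, given the cytokeratin area median, the implied IRS/H-score
  medians sit near the published 2.06/110.44. The intensity mix is
  marker-independent by design — a known simplification; per-marker
  score medians other than cytokeratin's are not matched.
* **Cell percentages**: HME matched to each marker's published
  range/median; NME (calponin only) beta-matched to mean 8.00%,
  SD 4.59% on [1.62, 22]; SME is the complement to 100. Structural
  counts are exact: the 8 lowest NME latent scores become NME-free
  tumors (111/119 positive), the 4 lowest HME latents become
  solely-spindle tumors (115/119 with both morphologies), and 9 tumors
  are flagged ineligible for area measurement (110 analyzed).

### Correlation planting

Named Spearman targets (defaults: NME–tubular 0.214, NME–mitoses
−0.147, NME–grading −0.157, HME–age 0.139) are induced by a Gaussian
copula: latent normal scores receive Pearson correlation
$r = 2\sin(\pi\rho_S/6)$ — the exact inverse of the bivariate-normal
rank-correlation relation — and every marginal transform is monotone in
its latent score (structural zeros are assigned to the lowest latents,
which is itself monotone), so Spearman correlations survive the
back-transform. Discreteness (mitoses, grading scores) and
zero-truncation attenuate the realized values slightly; Monte-Carlo
averaging over 200 cohorts recovers each target within ±0.05, which is
the fidelity claimed. An infeasible (non-positive-semi-definite) target
matrix is rejected with a diagnostic naming the most implicated pair.
Because SME is a deterministic complement, its (negative) association
with age emerges rather than being planted. Missingness is completely
at random, applied after correlation planting; its mechanism in real
archives is unknowable from summary counts, and MCAR is the neutral
choice. One consequence: per-analysis case counts for age against the
HME/NME subsets fluctuate around 94±2 rather than reproducing any fixed
printed value; the battery always reports the cases actually used.

## The synthetic tiles

`generate_tile()` renders each intensity class inside a distinct DAB OD
band (negative [0, 0.05], weak [0.19, 0.36], moderate [0.44, 0.76],
strong [0.84, 1.20]) with hematoxylin counterstain, through the same
Beer–Lambert forward model the deconvolution inverts, so the
quantification oracle is exact: every band keeps ≥ 0.04 OD margin from
its classification threshold, which 8-bit quantization error (< 0.01
OD at the rendered intensities) cannot bridge. Class pixel counts
follow the requested fractions exactly (largest-remainder
apportionment) and pixels are laid out by seeded random permutation, so
content is high-frequency while illumination drift is low-frequency —
the regime in which flat-fielding is identifiable. Defaults emulate
realistic acquisition: multiplicative left-to-right fall-off of
amplitude 0.1 and additive intensity noise of SD 1.5 gray levels, the
largest value for which a 3σ perturbation at the darkest class
boundary stays inside the band margin. What the tiles deliberately do
**not** model: nuclear texture, gland architecture, stain co-occurrence
within a pixel, chromatic camera noise, or whole-slide geometry —
passing the tile oracle shows the measurement chain is correct, not
that thresholds are right for any real staining batch.

```{r tile-demo}
tg <- generate_tile(tile_spec(width = 64, height = 64), seed = 1)
quantify_tile(tg$tile)
tg$truth$fractions
```

## The statistics battery

`run_battery()` executes, for each configured pair, a simple
one-predictor linear model with the F test from ANOVA comparison
against the intercept-only model, plus a tie-corrected Spearman rank
correlation (t approximation) for numeric predictors. Minimal
one-predictor models are the implemented reading of the source
methodology, which names only "lm" and single-stratum ANOVA without
covariates. Cases are pairwise-complete per analysis; the HME and NME
responses are analyzed over the tumors in which those categories exist
(115 and 111 under defaults). Category contrasts (age ≤ 5 vs > 5
years, f vs fs) run through the same linear-model pathway, where the
two-level F test is algebraically the pooled two-sample t test. No
multiplicity correction is applied by default, matching per-test
α = 0.05 reporting; `holm_adjust = TRUE` in the pipeline configuration
adds a Holm-adjusted column. Spearman estimates are reported for every
numeric pair, significant or not, with their signs — relevant because
summary tables in this literature sometimes print only significant
rows, or drop a sign.

```{r battery-demo}
coh <- generate_cohort(cohort_params(), seed = 1)
bat <- run_battery(coh)
subset(bat, parameter_2 == "calponin_pct_nme",
       select = c(parameter_1, n, p_value, rho))
```

`compare_marker_areas()` contrasts cytokeratin against each
myoepithelial marker on total positive area, IRS and H-score over the
area-eligible tumors, and reports per-marker medians;
`cohort_summary()` produces the headline count ratios, rounded half-up
to the conventional printed precision (e.g. 111/119 → 93%,
115/119 → 96.6%).

## Reproducibility and problem sizes

All randomness descends from one root seed through named substreams
(cohort, tiles, cells), so `run_pipeline()` output is bit-identical for
a fixed (config, seed), which the manifest records alongside a
configuration fingerprint. The test-suite problem sizes — cohorts of
119 tumors, tiles up to 100×100 px, 200 replicate cohorts for
correlation recovery, 1000 replicates for type-I calibration — were
chosen so the full statistical claims are exercised at the study's own
scale while the whole suite runs in well under a minute.

## Known limitations

* Intensity thresholds and stain vectors are defaults, not
  calibrations; real batches need their own.
* Artifact rejection (e.g. unspecific staining of secretory material)
  is not automated; area eligibility is an input flag, mirroring how
  such exclusions are made in practice.
* The cohort generator leaves unspecified variable pairs uncorrelated
  (e.g. mitotic count vs grading score, which are mechanistically
  linked through the grading system) — adequate for testing the
  battery, not for simulating biology.
* The NME percentage is modeled on one scale (percent of
  marker-positive cells); published accounts sometimes mix this with
  percent-of-all-tumor-cells scales, and their subset conventions
  (range over positive tumors vs all tumors) differ by source.
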