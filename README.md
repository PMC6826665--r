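# ihcarea

Area-based quantification of DAB immunohistochemistry and myoepithelial
cell statistics for mammary carcinoma cohorts.

## What it is for

Pathology studies of mammary carcinoma quantify two things per tumor and
marker (cytokeratin AE1/AE3, smooth muscle actin, vimentin, calponin):
the fraction of the epithelial tumor area that stains — split into weak,
moderate and strong DAB intensity — and the composition of the stained
cells: spindle-shaped non-neoplastic myoepithelial cells (SME),
hypertrophic myoepithelial cells (HME), and neoplastic cells with
myoepithelial differentiation (NME). These readouts are then correlated
with signalment and histology (age, sex, tubular growth %, mitotic
count/10 HPF, Elston–Ellis grading score) across the cohort.

`ihcarea` implements this pipeline end to end:

* **Stain quantification** — retrospective flat-field illumination
  correction, Ruifrok–Johnston color deconvolution onto H-DAB reference
  vectors (per-pixel optical density `OD = -log10(I/255)`), half-open
  intensity-class thresholds, and per-class area percentages of the
  analyzed area.
* **Area-based scores** — `IRS_area = (W + 5M + 10S)/100` (range 0–10)
  and `H_area = W + 2M + 3S` (range 0–300) from the weak/moderate/strong
  area percentages, with per-tumor averaging over up to three fields.
* **Cell metrics** — SME/HME/NME percentage aggregation from per-cell
  annotation tables, a spindle-vs-polygonal shape dichotomy, and the
  grading-score → grade mapping (3–5 → I, 6–7 → II, 8–9 → III).
* **Statistics battery** — one-predictor linear models with ANOVA model
  comparison, tie-corrected Spearman rank correlations, two-level
  category contrasts, marker-area comparisons, and cohort summary
  counts.
* **Synthetic data** — a Gaussian-copula cohort generator with planted
  Spearman correlations and study-matched marginals, and an image-tile
  generator with pixel-exact ground truth rendered through the same
  Beer–Lambert model the deconvolution inverts.

## Worked example

```r
library(ihcarea)

# a synthetic tile with known class fractions, quantified back
tg <- generate_tile(tile_spec(width = 64, height = 64), seed = 1)
quantify_tile(tg$tile)
#> <area_profile> negative 39.99% | weak 29.98% | moderate 19.97% | strong 10.06% (positive 60.01%)

# the two area-based scores on a published example readout
irs_area(44.86, 20.76, 15.83)     #> 3.0696
h_score_area(44.86, 20.76, 15.83) #> 133.87

# a full simulated cohort and its statistics
coh <- generate_cohort(cohort_params(), seed = 1)
s <- cohort_summary(coh)
s$pct_nme_positive   #> 93    (111/119 tumors with calponin-positive tumor cells)
s$pct_both_shapes    #> 96.6  (115/119 with both myoepithelial morphologies)

bat <- run_battery(coh)
subset(bat, parameter_1 == "tubular_growth" & parameter_2 == "calponin_pct_nme")
#>      parameter_1      parameter_2   n               test estimate  p_value    rho    rho_p significant
#> 12 tubular_growth calponin_pct_nme 111 lm+ANOVA, Spearman  0.06803 0.004987 0.2796 0.002961        TRUE
```

The battery reports, per analysis, the pairwise-complete case count, the
linear-model F-test p-value, and (for numeric pairs) the Spearman rho
with its t-approximation p-value. A single-cohort rho fluctuates around
its planted value (0.214 here) with SE ≈ 0.09; the Monte-Carlo recovery
of the planted values is part of the test suite.

The full pipeline (simulate → quantify → score → cells → statistics)
runs from one configuration and seed, and is bit-reproducible:

```r
bundle <- run_pipeline(list(seed = 7))
bundle
#> <report_bundle>
#>   cohort: 119 tumors (110 area-eligible)
#>   battery: 18 analyses, 2 significant at 0.05
#>   seed 7, config 00787078
```

A thin command-line wrapper is installed at
`inst/scripts/ihc-pipeline.R`
(`Rscript ihc-pipeline.R --config cfg.yaml --out-dir out/`).

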