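# octamv

Quantification of macular microvasculature on en-face OCTA angiograms, and
statistical analysis of how those metrics change across diabetic
retinopathy (DR) severity.

In DR, capillary nonperfusion worsens with disease stage: vessel densities
of the superficial (SCP) and deep (DCP) retinal capillary plexuses fall and
the foveal avascular zone (FAZ) enlarges. `octamv` is for researchers who
need this measurement chain reproducible end to end:

* **Image quantification.** Dual binarization of a 3 × 3 mm en-face
  angiogram (Frangi-type Hessian vesselness ∩ exact local-median adaptive
  threshold), topology-preserving Guo–Hall skeletonization, then

  * perfusion density `PD = 100 · |vessel ∩ R| / |R|` (%),
  * skeleton vessel density `SVD = 100 · L / (|R| − |R ∩ FAZ|)` (%),
  * FAZ area = on-pixels · p² (mm²),

  with full-frame and parafovea (1–3 mm annulus) regions.
* **Cohort inference from summaries.** SSI quality filtering (cutoff 55),
  one-way ANOVA with Bonferroni post-hoc tests, and the linear
  trend-contrast F across the four ordered groups
  (healthy < no-DR < NPDR < PDR),
  `F = (Σ cᵢ x̄ᵢ)² / (MSw Σ cᵢ²/nᵢ)` with coefficients (−3, −1, 1, 3) —
  all computable directly from per-group (n, mean, SD), so published
  summary tables are usable inputs.
* **Discrimination.** Empirical ROC/AUC (midrank Mann–Whitney) with Youden
  cutoffs, plus the closed-form binormal-mixture reconstruction
  `AUC = Σⱼ wⱼ Φ(|μ₀ − μⱼ| / √(σ₀² + σⱼ²))` for DR (NPDR + PDR pooled) vs
  healthy eyes, with a Monte-Carlo cross-check.
* **Synthetic data.** A seeded vessel-tree generator with exported ground
  truth (segment list, centreline length, FAZ disc), severity-dependent
  capillary dropout, and an OCTA-like renderer — so the whole pipeline is
  testable without patient data.

A 116-eye reference summary table (41/25/27/23 eyes per severity group,
eight macular metrics) ships with the package
(`reference_group_summaries()`) and drives the worked examples below.

## Worked example

Quantify one synthetic NPDR-like eye (25% capillary dropout, 0.34 mm FAZ):

```r
library(octamv)
tree <- generate_vessel_tree(seed = 101, faz_radius = 0.34)
tree <- apply_dropout(tree, fraction = 0.25, seed = 601)
img  <- render_angiogram(tree, width_px = 304, seed = 901)
faz  <- disc_mask(304, 304, 3/304, radius = 0.34)
quantify_image(img, faz)
#>     metric     value units region layer
#> 1       PD 8.1100675     %   full   SCP
#> 2      SVD 4.9930105     %   full   SCP
#> 3 FAZ_area 0.3614958  mm^2  FAZ    SCP
```

PD is the percent of frame area flagged as perfused vessel, SVD the
caliber-independent skeleton-length density (FAZ excluded from the
denominator), FAZ area the disc area in mm². Rerunning with a higher
dropout fraction lowers PD and SVD; enlarging the FAZ radius raises the
FAZ area — the severity ordering the cohort statistics then pick up.

Severity trend and discrimination for deep-plexus skeleton density, from
group summaries alone:

```r
rs <- reference_group_summaries()
tr <- trend_contrast_F(rs[rs$metric == "DCP_SVD", ])
unlist(tr[c("F", "df1", "df2", "p")])
#>            F          df1          df2            p
#> 3.291906e+02 1.000000e+00 1.120000e+02 3.942802e-35

sm <- rs[rs$metric == "DCP_SVD", ]
binormal_mixture_auc(sm[sm$group == "healthy", ],
  data.frame(weight = c(27, 23)/50, mean = sm$mean[3:4], sd = sm$sd[3:4]))
#> <auc_result> AUC = 0.980 (binormal_mixture; NA positive / NA negative)
```

The trend F ≈ 329 on (1, 112) df says DCP SVD falls in a strong linear
trend across severity groups; the AUC of 0.980 says it separates DR from
healthy eyes almost perfectly under the Gaussian model.

## Analysis workflow

The `analysis/` directory holds the numbered drivers for the full study,
each a thin script over the package functions, writing tables under
`results/` (bulky images under `scratch/`):

1. `01_simulate.R` — synthetic angiograms per severity preset + reference
   cohort sample;
2. `02_quantify.R` — PD/SVD/FAZ per eye, skeleton-length recovery vs truth;
3. `03_trend_stats.R` — ANOVA, Bonferroni and trend-F per metric;
4. `04_roc.R` — binormal, Monte-Carlo and empirical AUCs with Youden
   cutoffs.

`run_pipeline()` performs the same chain in one call. The methods vignette
(`vignettes/octa-microvascular-analysis.Rmd`) documents the models,
parameter defaults and design decisions.

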