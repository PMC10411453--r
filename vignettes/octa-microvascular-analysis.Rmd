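---
title: "Quantifying macular microvasculature on OCTA and relating it to diabetic retinopathy severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular microvasculature on OCTA and relating it to diabetic retinopathy severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamv)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
perfused retinal vasculature. In diabetic retinopathy (DR), capillary
nonperfusion progresses with disease severity: perfusion metrics of the
superficial (SCP) and deep (DCP) capillary plexuses fall, and the foveal
avascular zone (FAZ) enlarges. `octamv` implements the full quantitative
chain for a four-group severity design (healthy controls, diabetics without
retinopathy, non-proliferative DR, proliferative DR):

1. **image quantification** — binarize a 3 × 3 mm en-face angiogram
   (304 × 304 px by default), skeletonize it, and measure perfusion density
   (PD), skeleton vessel density (SVD) and FAZ area;
2. **cohort inference** — signal-strength quality filtering, one-way ANOVA
   with Bonferroni post-hoc tests, and a linear trend-contrast F across the
   ordered severity groups, all computable from per-group (n, mean, SD)
   summaries alone;
3. **discrimination** — empirical ROC curves with Youden cutoffs, and a
   closed-form binormal-mixture AUC reconstruction from group summaries;
4. **synthetic data** — a vessel-tree generator with exported ground truth,
   so that every stage is testable without patient data.

## Image quantification model

### Dual binarization

The vessel map is the intersection of two independent binarizations of the
normalized intensity image:

* **Hessian vesselness branch.** A Frangi-type tubularity filter: at each
  scale $\sigma$ the image is convolved with Gaussian second-derivative
  kernels, and from the Hessian eigenvalues $|\lambda_1| \le |\lambda_2|$
  (with $\sigma^2$ scale normalization) the response for bright curvilinear
  structure ($\lambda_2 < 0$) is
  $$V = \exp\!\left(-\frac{R_b^2}{2\beta^2}\right)
        \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
  \qquad R_b = \frac{\lambda_1}{\lambda_2},\;
  S = \sqrt{\lambda_1^2 + \lambda_2^2},$$
  maximized over scales. Defaults: scales $\{1, 2\}$ px (capillaries span
  roughly 1–4 px at 3/304 ≈ 0.0099 mm/px), $\beta = 0.5$, and $c$ set to
  half the maximal $S$ per scale. The response is thresholded globally with
  Otsu's method by default (a fixed threshold is configurable).
* **Local-median branch.** A pixel is vessel iff its intensity strictly
  exceeds the exact median of its window plus an offset. Defaults: 31 × 31
  px window (≈ 0.3 mm, an order of magnitude above capillary calibre, so
  the median tracks background rather than vessels) and offset 0.

Only pixels flagged by *both* branches survive; the combined map is by
construction a subset of each branch. The same dual map is used for PD and
as the input to skeletonization.

### Skeletonization and metrics

Thinning uses the two-subiteration Guo–Hall scheme: boundary pixels are
deleted in passes until the vessels are one pixel wide, preserving
8-connectivity. A conservative post-pass removes residual pixels that leave
a 2 × 2 all-on block, deleting only *simple points* (pixels whose removal
provably preserves local topology). One configuration is irreducible: a
perfectly even diagonal X-crossing leaves a 2 × 2 junction core in which no
pixel is simple; deleting any of them would disconnect an arm. Reference
thinning implementations leave the same core, and so does `octamv` —
topology wins over strict thinness in that measure-zero case.

The metrics, for a region mask $R$ and FAZ mask $F$:

* $\mathrm{PD} = 100 \cdot |\text{vessel} \cap R| / |R|$ (% of region area);
* $\mathrm{SVD} = 100 \cdot L / (|R| - |R \cap F|)$ with $L$ the skeleton
  length inside $R$;
* $\mathrm{FAZ\ area} = |F| \cdot p^2$ in mm² for pixel size $p$.

Two length metrics are available. The default **count** metric ($L$ =
skeleton pixel count) matches the familiar percent scale of clinical SVD
values and makes SVD with an empty FAZ exactly PD applied to the skeleton;
note that it is *resolution-dependent by construction* ($L/p$ over
$A/p^2$ scales with $p$), so SVD values are only comparable at a common
raster. The **geodesic** metric sums 8-neighbour links (orthogonal = 1 px,
diagonal = $\sqrt2$ px) and is the right choice when a physical length in
mm is wanted — it is what the ground-truth recovery tests use, since the
count metric systematically undercounts diagonal runs by up to
$1/\sqrt2$.

The FAZ outline itself is an *input* (clinically it is traced by hand);
only its area is computed here. The parafovea is the annulus between
diameters 1 mm and 3 mm about the fovea, rasterized by pixel-centre
inclusion.

## Cohort inference from summaries

All inference runs from per-group summaries $(n_i, \bar x_i, s_i)$, so
published summary tables are first-class inputs; when raw per-eye values
are available, `summarize_groups()` reduces them losslessly to the same
form (the two code paths agree to 1 × 10⁻⁹ relative F in tests).

With pooled within-group variance
$MS_w = \sum_i (n_i - 1) s_i^2 / (N - k)$:

* omnibus ANOVA: $F = \frac{\sum_i n_i(\bar x_i - \bar x)^2 / (k-1)}{MS_w}$
  on $(k - 1, N - k)$ df;
* linear trend contrast: for coefficients $c_i$ with $\sum c_i = 0$,
  $$F_{\text{trend}} = \frac{(\sum_i c_i \bar x_i)^2}
    {MS_w \sum_i c_i^2 / n_i}$$
  on $(1, N - k)$ df — the "p for trend" across ordered severity groups;
* Bonferroni post-hoc: pairwise t tests on the pooled $MS_w$ with p values
  multiplied by $\binom{k}{2}$ and capped at 1.

The default contrast is the equally spaced, unweighted linear contrast
$(-3, -1, 1, 3)$ for four ordered groups. This construction was an open
design choice — trend tests can also be built with group-size-weighted or
unevenly spaced scores — and the unweighted equally spaced form was chosen
because it is the textbook polynomial contrast for four ordered categories
and because it reproduces the published trend F statistics that ship with
the package as reference values (within 1% for six of the eight metrics;
the two that depend most sensitively on second-decimal rounding of the
printed means agree within 5–6%). The F statistic is invariant to
rescaling the coefficients, and with two groups and $(-1, 1)$ it reduces
to the omnibus F.

Equal variances are assumed (plain ANOVA pooling, no Welch correction),
and eyes are treated as independent; eye-within-patient correlation is out
of scope.

## Discrimination

`empirical_roc()` sweeps thresholds over the distinct score values with
ties grouped; metrics that *decrease* with disease (all densities) use the
`"lower"` orientation, which negates scores internally, while FAZ area is
used as-is. The AUC is the trapezoidal area, identical to the midrank
Mann–Whitney statistic $P(s_{pos} > s_{neg}) + \tfrac12 P(\text{tie})$ —
tests verify exact agreement with an $O(n^2)$ pair-count oracle. The
Youden cutoff maximizes sensitivity + specificity, breaking ties toward
higher specificity, and is reported on the original metric scale together
with the calling direction.

When only group summaries are available, the AUC for DR vs healthy is
reconstructed under a Gaussian model with the diseased class a mixture of
the NPDR and PDR components weighted by group size:
$$\mathrm{AUC} = \sum_j w_j\,
  \Phi\!\left(\frac{|\mu_{neg} - \mu_j|}{\sqrt{\sigma_{neg}^2 + \sigma_j^2}}\right).$$
Two compositional choices were open and are resolved as follows: positives
are NPDR ∪ PDR and negatives are the *healthy eyes only* (diabetics
without retinopathy are excluded from the ROC), because discriminating
clinical DR from healthy eyes is the stated task and because this
composition reproduces the published AUC panel within ±0.02 for every
metric. `monte_carlo_auc()` provides a stochastic cross-check that
converges to the closed form (within ±0.005 at 10⁵ samples per class in
the tests). No confidence intervals are computed.

## The synthetic generator

`generate_vessel_tree()` grows a stochastic branching network: four
arteriolar trunks enter mid-edge and branch toward the centre, widths
shrinking geometrically with depth (trunk 0.045 mm, decay 0.80/level,
floor 0.010 mm), every centreline stopping at the FAZ disc boundary.
`apply_dropout()` removes a fraction of the capillary-calibre segments
(width < 0.025 mm; trunks are protected, mirroring the observation that
perfusion loss in DR is predominantly capillary). Removal order is a fixed
seed-determined permutation, so masks at increasing fractions are nested
and PD/SVD are guaranteed non-increasing in the dropout fraction.
`render_angiogram()` rasterizes at 304 px over 3 mm and applies
multiplicative speckle (SD 0.25) on the vessel signal plus additive
Gaussian background (level 0.10, SD 0.04), clipped to [0, 1]; all noise
set to zero reproduces the rasterized truth exactly.

Severity presets used by the pipeline and the analysis scripts: dropout
0 / 0.05 / 0.25 / 0.50 and FAZ radius 0.32 / 0.33 / 0.34 / 0.37 mm (disc
areas ≈ 0.32–0.43 mm², spanning the healthy-to-PDR range of clinical FAZ
areas), with per-eye FAZ radius jitter of SD 0.015 mm. These were fixed
once, to produce the clinically expected *orderings*; the generator makes
no claim to reproduce specific clinical magnitudes. What it does not
emulate: real OCTA speckle statistics and projection artifacts, capillary
loops/anastomoses (the truth is a forest of line segments), flow-dependent
signal, segmentation errors between plexuses, and motion artifacts.
Passing tests therefore demonstrate the *internal consistency* of the
measurement chain (ground-truth recovery, monotonicity under dropout),
not clinical accuracy on patient images.

## Numerical choices and degenerate inputs

* All windowed filters use reflective (edge-inclusive symmetric) padding.
* Gaussian derivative kernels are truncated at 3σ and corrected to zero DC,
  so constant images yield an exactly zero vesselness response and the
  response is invariant to intensity offsets.
* The local median is exact (order statistic, not histogram-quantized),
  computed by a small compiled kernel.
* Image normalization on read is min–max; a constant image maps to
  all-zeros rather than erroring, keeping batch runs alive.
* Ties in ROC scores get midrank half-credit; Youden ties resolve toward
  specificity.
* Degenerate regions (empty region, FAZ covering the region), zero
  within-group variance, non-zero-sum contrasts, single-class labels and
  malformed tables raise classed errors (`octamv_*`) rather than NA.
* Default raster 304 × 304 px over 3 × 3 mm (pixel 3/304 mm); rasterization
  is by pixel-centre inclusion, which keeps disc-area error below 2% for
  FAZ-sized discs.

## Problem sizes

The test suite and scripts are sized for a laptop-class single core: the
end-to-end pipeline test runs 12 eyes at 152 px; ground-truth recovery and
dropout monotonicity use full 304 px rasters; Monte-Carlo AUC checks use
10⁵ samples per class; the analysis scripts simulate 20 eyes at 304 px.
The statistical engines are closed-form on summaries and effectively
instantaneous at any cohort size.

## Known limitations

* PD/SVD from the dual binarization are detection-limited at coarse
  rasters: capillaries thinner than a pixel are inconsistently detected,
  so absolute values are comparable only at a fixed resolution (count-based
  SVD additionally scales with pixel size by construction, see above).
* Device-computed vessel density (VD) is accepted only as a cohort-table
  column; the package does not emulate the scanner's proprietary VD, nor
  SSADA decorrelation, layer segmentation or projection-artifact removal.
* FAZ segmentation is not automated; masks are inputs.
* The binormal-mixture AUC is exact only under the Gaussian model; with
  heavy-tailed or skewed metric distributions the empirical ROC on raw
  values is the primary tool.
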