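Package: octamv
Title: OCTA Microvascular Quantification and Diabetic Retinopathy Severity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies en-face optical coherence tomography angiography
    (OCTA) images of the macular microvasculature and relates the resulting
    metrics to diabetic retinopathy (DR) severity. Provides dual binarization
    (Frangi-type Hessian vesselness combined with a local-median adaptive
    threshold), topology-preserving skeletonization, perfusion density (PD),
    skeleton vessel density (SVD) with foveal avascular zone (FAZ) exclusion,
    FAZ area and parafovea geometry; signal-strength quality filtering;
    one-way ANOVA with Bonferroni post-hoc tests and linear trend-contrast
    F statistics computable directly from per-group (n, mean, SD) summaries;
    empirical ROC curves with Youden cutoffs and closed-form binormal-mixture
    AUC reconstruction. A synthetic angiogram and cohort generator with
    exported ground truth makes the full pipeline testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
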