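Package: radpt
Title: Peri-Tumoral and Intra-Tumoral Radiomics for Prostate Cancer Risk Stratification
Version: 0.1.0
Authors@R:
    person("radpt", "maintainers", email = "radpt@example.org", role = c("aut", "cre"))
Description: Risk stratification of prostate cancer lesions from bi-parametric
    MRI (T2-weighted and ADC) using texture radiomics of the lesion and of
    annular peri-tumoral rings (3 mm bands out to 12 mm, clipped to the
    prostate). Provides a synthetic phantom cohort generator, geometric and
    intensity preprocessing, a 150-feature-per-sequence 2D texture battery
    (signal intensity, first-order, Gabor, Haralick, Laws, with CoLlAGe as an
    optional extension), Wilcoxon rank-sum prefiltering with
    minimum-redundancy-maximum-relevance feature ranking, quadratic
    discriminant classification with patient-grouped repeated cross-validation,
    and ROC/PI-RADS comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
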