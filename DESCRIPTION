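Package: longmorph
Title: Longitudinal Brain Morphometry with Mixed-Effect Atrophy-Rate Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal regional brain morphometry
    (atlas-based volumes, planar areas, and cortical thickness) in cohorts of
    Parkinson's disease patients and healthy controls. Provides reference
    normalization of regional values to intracranial volume or mean cortical
    thickness, control-derived age and education covariate correction, robust
    locally weighted scatterplot smoothing (LOWESS) for exploratory trajectory
    analysis, restricted maximum likelihood (REML) linear mixed-effect models
    with a piecewise (knotted) age effect and contrast F-tests of group-specific
    atrophy rates, a cross-sectional test battery (Welch t, Pearson chi-square,
    Fisher exact, Kruskal-Wallis, Spearman, Lilliefors, Bonferroni), a
    mild-cognitive-impairment converter comparison, and a synthetic longitudinal
    cohort generator emulating group trajectories, knotted age effects,
    subject-level random effects, and monotone study attrition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    lmerTest,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
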