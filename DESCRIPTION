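Package: eldermicro
Title: Longitudinal Gut Metagenome Analysis for Dementia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline linking longitudinal gut metagenomes of
    nursing-home elders to dementia status and to intestinal P-glycoprotein
    expression. Provides a synthetic cohort generator with planted effects,
    Jaccard beta diversity with a permutation-based PERMANOVA, a
    zero-inflated beta mixed model (random subject intercept, adaptive
    Gauss-Hermite quadrature) for genus-level differential abundance, a
    multi-seed subsample-and-consensus random-forest feature-selection
    protocol for repeated-measures designs, restricted-versus-full
    random-forest regression comparison for P-glycoprotein prediction, and
    butyrate biosynthesis gene statistics (mixed-model contrasts and
    Spearman correlation with P-glycoprotein).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    randomForest,
    lme4
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
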