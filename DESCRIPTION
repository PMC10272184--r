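Package: mimicog
Title: Facial Mimicry, Confidence and Emotion Recognition Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studies relating facial mimicry
    and metacognitive confidence to emotion recognition. Provides facial-EMG
    preprocessing (band-pass filtering, rectification, 100-ms binning,
    distribution-based artifact rejection, baseline correction, within-subject
    z-scoring and trial/category averaging), slider-based emotion-recognition
    accuracy scoring, type-2 ROC metacognitive sensitivity (AUROC2),
    questionnaire scoring (social anxiety and autistic-trait scales) with
    chained-equation imputation and reliability estimation, and the
    trait-moderation statistics (binomial and Gaussian mixed models with
    crossed random intercepts, sum-coded category contrasts, cluster
    bootstrap). A synthetic-study generator with known ground truth makes the
    whole pipeline testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
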