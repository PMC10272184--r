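# mimicog

Facial mimicry, metacognitive confidence, and emotion recognition: a tested
R pipeline for psychophysiology studies of how social anxiety and autistic
traits moderate emotion perception.

## What it is for

Studies in this area show participants short videos of emotional facial
expressions (anger, fear, happiness, sadness, surprise, neutral), record
facial EMG over the corrugator supercilii ("frowning" muscle) and
zygomaticus major ("smiling" muscle) during passive viewing, and then ask
participants to label each expression with six 0–100 sliders and rate their
confidence. `mimicog` implements the complete analysis for such designs:

* **EMG preprocessing** — zero-phase 28–500 Hz band-pass + 50 Hz notch,
  full-wave rectification, 100-ms binning into fixation / baseline /
  response / post epochs, ±3.5 SD distribution-based artifact rejection with
  strict >50% trial-exclusion rules, baseline correction, per-subject
  z-scoring, and trial/category averaging.
* **Behaviour scoring** — accuracy as the unique slider argmax (tied maxima
  discounted) and relative accuracy (true-category slider minus the mean of
  the rest).
* **Metacognition** — per-subject type-2 ROC curves over the 11-point
  confidence grid and their area (AUROC2),
  `AUROC2 = area under {P(conf ≥ c | correct) vs P(conf ≥ c | incorrect)}`,
  with Mahalanobis outlier screening and Pearson/Spearman trait
  correlations using `t = r·√(n−2)/√(1−r²)`.
* **Questionnaires** — LSAS (48 items, 0–144) and AQ (50 items, dichotomous
  0–50, standard key) scoring, chained-equation (PMM) imputation,
  Cronbach's α with bootstrap CI, moments and cut-off tallies.
* **Moderation statistics** — binomial/Gaussian mixed models with sum-coded
  emotion category, standardized trait, their interaction, and crossed
  random intercepts for subject and stimulus (`lme4`); reconstruction of the
  omitted category via general hypothesis z-tests; per-emotion
  EMG→accuracy GLMMs; cluster-bootstrap linear models on category-averaged
  EMG.
* **Synthetic studies** — a generator that emulates the whole design (trait
  distributions, 6×10×2 stimulus schedule, trait-modulated accuracy and
  confidence, emotion-specific EMG responses, injected artifacts) with
  known ground truth, so every stage is testable without participant data.

## Worked example

```r
library(mimicog)

sim    <- simulate_study(n_subjects = 57, effects = sim_effects(), seed = 42,
                         emg = "epochs")
scored <- score_ratings(sim$ratings$ratings)
round(tapply(scored$correct, scored$true_category, mean, na.rm = TRUE), 3)
#>     anger      fear happiness   neutral   sadness  surprise
#>     0.611     0.121     0.947     0.816     0.300     0.837
```

Happiness is recognized almost at ceiling and fear worst — the difficulty
ordering the generator injects (its category effects are the log odds-ratios
reported for this paradigm). Metacognitive sensitivity and its link to
autistic traits:

```r
mc <- compute_metacognition(scored)
head(mc, 3)
#>   subject_id    auroc2 n_correct n_incorrect
#> 1          1 0.8031727        37          23
#> 2          2 0.7412500        40          20
#> 3          3 0.6142344        38          22

ct <- metacog_trait_correlation(sim$traits$aq_total, mc$auroc2)
#> AQ-AUROC2: r = -0.804, t(55) = -10.04, p = 4.8e-14 (0 outlier(s) excluded)
```

AUROC2 is ~0.5 when confidence carries no information and 1 for perfect
confidence–correctness coupling; the negative correlation recovers the
generator's ground truth (metacognitive coupling decreasing with AQ). The
headline accuracy model:

```r
aq_z <- scale(sim$traits$aq_total)[, 1]
fit  <- fit_trait_category_model(scored, aq_z, outcome = "accuracy")
fit$coefficients[fit$coefficients$term == "trait_z", ]
#>    term   estimate     se statistic  p           odds_ratio
#> trait_z   -0.35334 0.0520   -6.7962  1.07e-11    0.7023

sum_coding_contrasts(fit)[1:6, c("level", "estimate", "z")]
#>       level   estimate          z
#>       anger -0.1472938  -1.664576
#>        fear -2.6966122 -20.968067
#>   happiness  2.3482921  13.841046
#>     sadness -1.4749606 -15.859837
#>    surprise  1.0671539   9.788695
#>     neutral  0.9034205   8.677314
```

The odds ratio 0.70 per AQ standard deviation recovers the injected negative
trait effect (−0.3 log-odds/SD, plus the extra fear penalty); the `neutral`
row is the omitted sum-coded category reconstructed by a general hypothesis
z-test, and the six deviations sum to zero.

The end-to-end pipeline (simulate → questionnaires → EMG → behaviour →
metacognition → models → `report.md`) runs with one call or from the shell:

```r
run_pipeline(pipeline_config(seed = 1, n_subjects = 57, out_dir = "out"))
```

```sh
Rscript inst/cli/mimicog.R run-all --seed 1 --out out/
```

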