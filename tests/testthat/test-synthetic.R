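test_that("trait generation is deterministic and hits the target moments", {
  a <- generate_traits(50, seed = 3)
  b <- generate_traits(50, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_traits(50, seed = 4)))

  tr <- generate_traits(10000, seed = 7)
  expect_lt(abs(mean(tr$lsas_total) - 38.53), 0.5)
  expect_lt(abs(sd(tr$lsas_total) - 17.53), 0.3)
  expect_lt(abs(cor(tr$lsas_total, tr$aq_total, method = "spearman")), 0.05)
  ## AQ totals positively skewed with the target moments
  expect_lt(abs(mean(tr$aq_total) - 16.38), 0.3)
  expect_lt(abs(sd(tr$aq_total) - 7.34), 0.3)
  expect_gt(mimicog:::moment_skewness(tr$aq_total), 0.8)
  ## totals recomputable from items
  lsas_items <- as.matrix(tr[c(paste0("lsas_f", 1:24), paste0("lsas_a", 1:24))])
  expect_equal(unname(score_lsas(lsas_items)), tr$lsas_total)
  expect_error(generate_traits(50, trait_params(lsas_sd = -1)),
               class = "mimicog_parameter_error")
  expect_error(generate_traits(1), class = "mimicog_parameter_error")
})

test_that("generated LSAS items reach questionnaire-grade internal consistency", {
  tr <- generate_traits(1000, seed = 8)
  items <- tr[c(paste0("lsas_f", 1:24), paste0("lsas_a", 1:24))]
  a <- cronbach_alpha(items, n_boot = 0)$alpha
  expect_gt(a, 0.85)
  expect_lt(a, 0.97)
})

test_that("the design has 60 stimuli, 120 passive and 60 recognition trials per subject", {
  de <- generate_design(4, seed = 5)
  expect_equal(nrow(de$stimuli), 60)
  expect_equal(as.integer(table(de$stimuli$category)), rep(10L, 6))
  expect_equal(anyDuplicated(de$stimuli$stimulus_id), 0L)
  for (s in 1:4) {
    pv <- de$passive[de$passive$subject_id == s, ]
    expect_equal(nrow(pv), 120)
    expect_equal(as.integer(table(pv$stimulus_id)), rep(2L, 60))   # each stimulus twice
    expect_equal(sort(unique(pv$presentation)), c(1L, 2L))
    rc <- de$recognition[de$recognition$subject_id == s, ]
    expect_equal(nrow(rc), 60)
    expect_equal(anyDuplicated(rc$stimulus_id), 0L)
  }
})

test_that("ratings saturate at huge discriminability and are internally consistent", {
  eff <- sim_effects(accuracy_intercept = 20,
                     category_effects = setNames(rep(0, 6), mimicog:::EMOTION_CATEGORIES),
                     b_aq_accuracy = 0, b_aq_fear_extra = 0)
  tr <- generate_traits(10, seed = 2)
  de <- generate_design(10, seed = 2)
  ra <- generate_ratings(tr, de, eff, seed = 2)
  acc <- score_accuracy(ra$ratings)
  expect_true(all(acc == 1))
  ## slider vector consistent with drawn correctness in the general case
  ra2 <- generate_ratings(tr, de, sim_effects(), seed = 3)
  acc2 <- score_accuracy(ra2$ratings)
  expect_identical(unname(acc2), as.numeric(ra2$ground_truth$correct))
  ## determinism
  expect_identical(generate_ratings(tr, de, seed = 5)$ratings,
                   generate_ratings(tr, de, seed = 5)$ratings)
})

test_that("zero metacognitive coupling gives chance-level AUROC2", {
  eff <- sim_effects(metacog_coupling_base = 0, metacog_coupling_aq = 0)
  sim <- simulate_study(84, eff, seed = 6, emg = "none")   # ~5000 trials
  mc <- compute_metacognition(score_ratings(sim$ratings$ratings))
  expect_lt(abs(mean(mc$auroc2, na.rm = TRUE) - 0.5), 0.02)
})

test_that("the injected trait-accuracy slope is recovered by a direct logistic fit", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_study(200, sim_effects(b_aq_accuracy = -0.3), seed, emg = "none")
    d <- data.frame(correct = score_accuracy(sim$ratings$ratings),
                    aq_z = sim$ratings$ground_truth$aq_z[sim$ratings$ratings$subject_id])
    fit <- glm(correct ~ aq_z, binomial, data = d)
    hits <- hits + (coef(fit)["aq_z"] < 0)
  }
  expect_gte(hits, 19L)
})

test_that("EMG generation is deterministic and honours parameter bounds", {
  tr <- generate_traits(3, seed = 9)
  de <- generate_design(3, seed = 9)
  e1 <- generate_emg(tr, de, seed = 9)
  e2 <- generate_emg(tr, de, seed = 9)
  expect_identical(e1$epochs, e2$epochs)
  expect_identical(e1$ground_truth$artifact_mask, e2$ground_truth$artifact_mask)
  expect_error(sim_effects(artifact_rate = 1.5), class = "mimicog_parameter_error")
  expect_error(sim_effects(b_aq_accuracy = Inf), class = "mimicog_parameter_error")
})

test_that("raw EMG signals are reproducible under a fixed seed", {
  tr <- generate_traits(2, seed = 10)
  de <- generate_design(2, seed = 10)
  r1 <- generate_emg(tr, de, seed = 10, raw = TRUE, subjects = 1)
  r2 <- generate_emg(tr, de, seed = 10, raw = TRUE, subjects = 1)
  expect_identical(r1$signal, r2$signal)
  expect_equal(nrow(r1$markers), 120)
  expect_true(all(diff(r1$markers$onset_ms) > 0))
})
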