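## Small simulated studies are reused across model tests.
sim40 <- simulate_study(40, seed = 71, emg = "none")
scored40 <- score_ratings(sim40$ratings$ratings)
aq_z40 <- sim40$ratings$ground_truth$aq_z

test_that("fit_mixed returns coefficient tables with ORs and omnibus tests", {
  fit <- fit_trait_category_model(scored40, aq_z40, "accuracy", nAGQ = 0,
                                  omnibus = TRUE)
  cf <- fit$coefficients
  expect_true(all(c("term", "estimate", "se", "statistic", "p", "odds_ratio") %in% names(cf)))
  expect_equal(cf$odds_ratio, exp(cf$estimate))          # OR = exp(beta) exactly
  expect_true(is.data.frame(fit$omnibus))
  expect_setequal(fit$omnibus$term, c("category", "trait_z", "category:trait_z"))
  expect_equal(fit$omnibus$df[fit$omnibus$term == "category"], 5)
  expect_true(all(fit$omnibus$p >= 0 & fit$omnibus$p <= 1))

  fitc <- fit_trait_category_model(scored40, aq_z40, "confidence", omnibus = TRUE)
  expect_equal(unique(fitc$omnibus$test), "F")
  expect_true(all(is.finite(fitc$coefficients$df)))
})

test_that("sum-coded deviations sum to zero and the omitted level matches the delta-method oracle", {
  fit <- fit_trait_category_model(scored40, aq_z40, "accuracy", nAGQ = 0)
  sc <- sum_coding_contrasts(fit)
  for (blk in unique(sc$block)) {
    d <- sc[sc$block == blk, ]
    expect_equal(sum(d$estimate), 0, tolerance = 1e-8)
    expect_equal(nrow(d), 6)
  }
  ## brute-force delta method for the omitted (neutral) main deviation
  V <- as.matrix(vcov(fit$model))
  nm <- grep("^category[0-9]+$", colnames(V), value = TRUE)
  se2 <- 0
  for (i in nm) for (j in nm) se2 <- se2 + V[i, j]
  d <- sc[sc$block == "main", ]
  expect_equal(d$se[d$level == "neutral"], sqrt(se2), tolerance = 1e-12)
  ## 5 deviations of +1 reconstruct to -5 (identity on the point estimate)
  est <- lme4::fixef(fit$model)[nm]
  expect_equal(d$estimate[d$level == "neutral"], -sum(est))
})

test_that("with no true random variance, glmer fixed effects match plain glm", {
  set.seed(72)
  n <- 2000
  d <- data.frame(subject_id = factor(rep(1:40, each = 50)),
                  stimulus_id = factor(rep(1:50, 40)),
                  x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.3 + 0.5 * d$x))
  fit <- fit_mixed(y ~ x + (1 | subject_id) + (1 | stimulus_id), d,
                   family = "binomial", nAGQ = 0, omnibus = FALSE)
  ref <- glm(y ~ x, binomial, d)
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ref)))), 1e-2)
  expect_true(fit$converged || any(grepl("singular", fit$messages)))
})

test_that("fit_lm_category_emg recovers injected effects and bootstraps reproducibly", {
  cats <- mimicog:::EMOTION_CATEGORIES
  subs <- 1:25
  d <- expand.grid(subject_id = subs, category = cats, stringsAsFactors = FALSE)
  delta <- 0.8
  d$value <- ifelse(d$category == "anger", delta, 0)    # zero noise
  tz <- rep(0, length(subs))
  fit <- fit_lm_category_emg(d, tz, n_boot = 50, seed = 4)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "categoryanger"], delta, tolerance = 1e-12)
  ## neutral is the reference: intercept 0
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 0, tolerance = 1e-12)

  set.seed(99)  # bootstrap must not depend on the ambient RNG state
  fit2 <- fit_lm_category_emg(d, tz, n_boot = 50, seed = 4)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_warning(fit_lm_category_emg(d[d$subject_id <= 10, ], tz[1:10], n_boot = 10),
                 "fewer than 20")
})

test_that("cluster-bootstrap percentile intervals achieve nominal coverage", {
  truth <- 0.6
  cats <- mimicog:::EMOTION_CATEGORIES
  cover <- 0L
  n_sim <- 60
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    subs <- 1:30
    d <- expand.grid(subject_id = subs, category = cats, stringsAsFactors = FALSE)
    u <- rnorm(length(subs), 0, 0.3)                    # subject random effect
    d$value <- truth * (d$category == "anger") + u[d$subject_id] +
      rnorm(nrow(d), 0, 0.5)
    tz <- rnorm(length(subs))
    fit <- suppressWarnings(fit_lm_category_emg(d, tz, n_boot = 200, seed = s))
    cf <- fit$coefficients
    i <- which(cf$term == "categoryanger")
    cover <- cover + (cf$ci_low[i] <= truth && truth <= cf$ci_high[i])
  }
  expect_gte(cover / n_sim, 0.85)   # ~95% nominal, binomial noise at n_sim = 60
  expect_lte(cover / n_sim, 1.00)
})

test_that("fit_emg_accuracy uses the conventional muscle sets and flags separation", {
  sim <- simulate_study(40, seed = 73, emg = "epochs")
  sc <- score_ratings(sim$ratings$ratings)
  pre <- preprocess_emg(sim$emg, sim$design$stimuli)
  tz <- sim$ratings$ground_truth$aq_z
  fh <- fit_emg_accuracy(sc, pre$trial_avg, "happiness", tz, nAGQ = 0)
  expect_true(all(c("corrugator", "zygomaticus", "trait_z:corrugator",
                    "trait_z:zygomaticus") %in% fh$coefficients$term))
  fs <- fit_emg_accuracy(sc, pre$trial_avg, "sadness", tz, nAGQ = 0)
  expect_true("corrugator" %in% fs$coefficients$term)
  expect_false("zygomaticus" %in% fs$coefficients$term)

  ## deterministic EMG -> correctness mapping is quasi-separated
  sep <- sc[sc$true_category == "sadness", ]
  e <- pre$trial_avg[pre$trial_avg$muscle == "corrugator", ]
  v <- e$value[match(paste(sep$subject_id, sep$stimulus_id),
                     paste(e$subject_id, e$stimulus_id))]
  sep$correct <- as.numeric(v > median(v, na.rm = TRUE))
  fsep <- suppressWarnings(
    fit_emg_accuracy(sep, pre$trial_avg, "sadness", tz, nAGQ = 0))
  expect_true(length(fsep$messages) > 0 || !fsep$converged ||
                any(grepl("separation", fsep$messages)))
})
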