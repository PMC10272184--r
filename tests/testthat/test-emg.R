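test_that("filter_rectify implements the 28-500 Hz band-pass with 50 Hz notch", {
  t <- seq_len(2000) / 1000
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(sqrt(mean(filter_rectify(s50)^2)) / sqrt(mean(s50^2)), 0.05)

  s10 <- sin(2 * pi * 10 * t)
  expect_lt(max(filter_rectify(s10)), 0.10)   # 4th-order high-pass at 28 Hz

  ## full-wave-rectified sinusoid: mean = 2a/pi (97 Hz avoids phase-locked
  ## sampling; discrete-time mean converges to the closed form)
  t4 <- seq_len(4000) / 1000
  a <- 2
  y <- filter_rectify(a * sin(2 * pi * 97 * t4))
  expect_equal(mean(y), 2 * a / pi, tolerance = 0.02)

  expect_true(all(filter_rectify(rnorm(1000)) >= 0))
  expect_error(filter_rectify(rnorm(100), fs = 500), class = "mimicog_parameter_error")
  expect_silent(filter_rectify(rnorm(100), fs = 500, allow_fs_override = TRUE))
  expect_error(filter_rectify(c(1, NA, 3)), class = "mimicog_validation_error")
})

test_that("epoch_and_bin averages 100-ms bins in the documented layout", {
  ## constant signal: every bin equals the constant
  n <- 6000
  mk <- data.frame(subject_id = 1L, trial = 1L, stimulus_id = "s1", onset_ms = 1000L)
  sig <- data.frame(subject_id = 1L, muscle = "corrugator",
                    t_ms = 0:(n - 1), value = 7)
  ep <- epoch_and_bin(sig, mk)
  expect_equal(nrow(ep), 45)
  expect_true(all(ep$value == 7))
  expect_equal(as.vector(table(ep$epoch)[c("fixation", "baseline", "response", "post")]),
               c(10L, 5L, 15L, 15L))

  ## step from 0 to 1 exactly at response onset (onset + 500 ms)
  v <- rep(0, n); v[(1000 + 500 + 1):n] <- 1
  sig$value <- v
  ep <- epoch_and_bin(sig, mk)
  expect_true(all(ep$value[ep$epoch == "baseline"] == 0))
  expect_true(all(ep$value[ep$epoch == "response"] == 1))

  ## linear ramp: bin means equal the ramp midpoints (analytic oracle)
  sig$value <- 0:(n - 1)
  ep <- epoch_and_bin(sig, mk)
  resp <- ep[ep$epoch == "response", ]
  midpoints <- 1500 + (resp$bin - 1) * 100 + (0 + 99) / 2
  expect_equal(resp$value, midpoints)

  ## truncated trial flagged excluded
  mk2 <- rbind(mk, data.frame(subject_id = 1L, trial = 2L, stimulus_id = "s2",
                              onset_ms = 5800L))
  ep2 <- epoch_and_bin(sig, mk2)
  expect_true(all(ep2$excluded[ep2$trial == 2]))
  expect_true(all(is.na(ep2$value[ep2$trial == 2])))

  ## overlapping markers are a design error
  mk3 <- rbind(mk, data.frame(subject_id = 1L, trial = 2L, stimulus_id = "s2",
                              onset_ms = 1500L))
  expect_error(epoch_and_bin(sig, mk3), class = "mimicog_design_error")
})

test_that("detect_artifacts flags nothing on zero-variance data", {
  M <- matrix(5, 20, 45)
  ep <- detect_artifacts(make_epochs(M))
  expect_false(any(ep$flagged))
  expect_false(any(ep$excluded))
})

test_that("detect_artifacts matches the brute-force z oracle on a spike fixture", {
  set.seed(101)
  vals <- matrix(rnorm(20 * 45), 20, 45)
  vals[3, 15 + 8] <- 10          # response bin 8 (interest bin 13) at +10 SD
  ep <- detect_artifacts(make_epochs(vals))
  M <- vals[, 11:30]             # the 20 interest bins
  FL <- oracle_artifact_flags(M)
  got <- epochs_interest(ep, "flagged")
  expect_identical(got, FL)
  expect_true(got[3, 13])
  expect_false(any(ep$excluded))                      # trial retained
  expect_true(is.na(epochs_interest(ep, "value")[3, 13]))  # flagged bin set missing
})

test_that("trials with >50% extreme bins are excluded entirely", {
  set.seed(102)
  vals <- matrix(rnorm(20 * 45), 20, 45)
  vals[5, 10 + (1:11)] <- 10     # 11 of 20 interest bins extreme
  ep <- detect_artifacts(make_epochs(vals))
  expect_true(all(ep$excluded[ep$trial == 5]))
  expect_true(all(is.na(ep$value[ep$trial == 5 & ep$epoch %in% c("baseline", "response")])))
  ## 3 of 5 baseline bins extreme also excludes
  vals2 <- matrix(rnorm(20 * 45), 20, 45)
  vals2[7, 11:13] <- 10
  ep2 <- detect_artifacts(make_epochs(vals2))
  expect_true(all(ep2$excluded[ep2$trial == 7]))
})

test_that("a lower z threshold flags a superset of bins", {
  set.seed(103)
  vals <- matrix(rnorm(30 * 45), 30, 45) + 3
  vals[cbind(sample(30, 5), sample(11:30, 5, replace = TRUE))] <- 9
  f35 <- detect_artifacts(make_epochs(vals), z_threshold = 3.5)$flagged
  f30 <- detect_artifacts(make_epochs(vals), z_threshold = 3.0)$flagged
  expect_true(all(f30[f35]))
  expect_gt(sum(f30), sum(f35))
})

test_that("baseline_correct subtracts the missing-aware baseline mean", {
  vals <- matrix(1, 2, 45)
  vals[, 16:30] <- 4                       # response bins
  ep <- baseline_correct(make_epochs(vals))
  expect_true(all(ep$value[ep$epoch == "response"] == 3))
  expect_true(all(ep$value[ep$epoch == "baseline"] == 1))  # baseline unchanged

  vals2 <- matrix(1, 1, 45); vals2[, 16:30] <- 2
  ep2 <- make_epochs(vals2)
  ep2$value[ep2$epoch == "baseline" & ep2$bin == 3] <- NA
  ep2 <- baseline_correct(ep2)
  expect_true(all(ep2$value[ep2$epoch == "response"] == 1))

  ## inverse identity on random data
  set.seed(104)
  vals3 <- matrix(rnorm(5 * 45), 5, 45)
  ep3 <- baseline_correct(make_epochs(vals3))
  bmean <- rowMeans(vals3[, 11:15])
  rec <- epochs_interest(ep3)[, 6:20] + bmean
  expect_equal(rec, vals3[, 16:30])

  ## all baseline bins missing excludes the trial
  vals4 <- matrix(rnorm(2 * 45), 2, 45)
  ep4 <- make_epochs(vals4)
  ep4$value[ep4$trial == 1 & ep4$epoch == "baseline"] <- NA
  ep4 <- baseline_correct(ep4)
  expect_true(all(ep4$excluded[ep4$trial == 1]))
  expect_true(all(is.na(ep4$value[ep4$trial == 1 & ep4$epoch == "response"])))
})

test_that("zscore_subject_muscle standardizes each subject-muscle pool independently", {
  set.seed(105)
  vals <- matrix(rnorm(10 * 45), 10, 45)
  ep1 <- make_epochs(vals, subject_id = 1L)
  ep2 <- make_epochs(vals * 50 + 7, subject_id = 2L)   # different scale
  ep <- structure(rbind(ep1, ep2), class = class(ep1), fs = 1000)
  z <- zscore_subject_muscle(ep)
  for (s in 1:2) {
    pool <- z$value[z$subject_id == s & z$epoch == "response"]
    expect_equal(mean(pool), 0, tolerance = 1e-10)
    expect_equal(sd(pool), 1, tolerance = 1e-10)
  }
  ## affine invariance: a*x + b (a > 0) gives identical z output
  za <- zscore_subject_muscle(transform(ep1, value = 3 * value + 2))
  zb <- zscore_subject_muscle(ep1)
  expect_equal(za$value[za$epoch == "response"], zb$value[zb$epoch == "response"])
  ## zero variance signalled
  flat <- make_epochs(matrix(1, 3, 45))
  expect_warning(zf <- zscore_subject_muscle(flat), "zero variance")
  expect_true(all(is.na(zf$value[zf$epoch == "response"])))
})

test_that("summarize_emg averages the last second, presentations and categories", {
  ## response bins 1-5 = 9, bins 6-15 = 2: trial summary must be 2
  vals <- matrix(0, 1, 45); vals[, 16:20] <- 9; vals[, 21:30] <- 2
  su <- summarize_emg(make_epochs(vals))
  expect_equal(su$trial_level$value, 2)

  ## presentation 1 excluded -> trial average falls back to presentation 2
  vals2 <- matrix(0, 2, 45); vals2[2, 21:30] <- 0.4
  ep <- make_epochs(vals2, stimulus_id = c("sA", "sA"), presentation = c(1L, 2L))
  ep$value[ep$trial == 1] <- NA
  su2 <- summarize_emg(ep)
  expect_equal(su2$trial_avg$value, 0.4)

  ## category mean of 10 trials valued 0.1..1.0
  vals3 <- matrix(0, 10, 45)
  vals3[, 21:30] <- matrix(seq(0.1, 1.0, 0.1), 10, 10)
  su3 <- summarize_emg(make_epochs(vals3, category = rep("sadness", 10)))
  expect_equal(su3$cat_avg$value, 0.55)
})

test_that("the pipeline is equivariant to positive rescaling of the signal", {
  tr <- generate_traits(3, seed = 31)
  de <- generate_design(3, seed = 31)
  em <- generate_emg(tr, de, seed = 31)
  p1 <- preprocess_emg(em, de$stimuli)
  em2 <- em
  em2$epochs$value <- em2$epochs$value * 4.2
  p2 <- preprocess_emg(em2, de$stimuli)
  expect_equal(p1$trial_avg$value, p2$trial_avg$value, tolerance = 1e-10)
})

test_that("clean simulations have few false flags and exclusions", {
  eff <- sim_effects(artifact_rate = 0)
  tr <- generate_traits(5, seed = 32)
  de <- generate_design(5, seed = 32)
  em <- generate_emg(tr, de, eff, seed = 32)
  ep <- detect_artifacts(em$epochs)
  int <- ep$epoch %in% c("baseline", "response")
  expect_lte(mean(ep$flagged[int]), 0.01)   # false-positive rate of the 3.5 SD rule
  frac_excl <- mean(tapply(ep$excluded, mimicog:::group_id(ep$subject_id, ep$muscle, ep$trial), any))
  expect_lte(frac_excl, 0.01)
})

test_that("injected 10 SD artifacts are recovered with sensitivity >= 0.9", {
  tr <- generate_traits(4, seed = 33)
  de <- generate_design(4, seed = 33)
  em <- generate_emg(tr, de, sim_effects(artifact_rate = 0.02), seed = 33)
  ep <- detect_artifacts(em$epochs)
  gtm <- em$ground_truth$artifact_mask
  int <- ep$epoch %in% c("baseline", "response")
  ib <- ifelse(ep$epoch == "baseline", ep$bin, 5L + ep$bin)
  flagged_keys <- paste(ep$subject_id, ep$trial, ep$muscle, ib)[ep$flagged & int]
  gt_keys <- paste(gtm$subject_id, gtm$trial, gtm$muscle, gtm$interest_bin)
  expect_gte(mean(gt_keys %in% flagged_keys), 0.9)
})

test_that("the raw-signal chain recovers an injected amplitude within 5%", {
  ## filter -> bin -> baseline-correct -> summarize, in amplitude units.
  ## Artifact screening is deliberately not part of this composition: with a
  ## single elevated category and near-zero background noise the 3.5 SD rule
  ## (correctly) treats the response itself as extreme; its false-positive
  ## behaviour on realistic noise has its own test below.
  eff <- sim_effects(artifact_rate = 0, mimicry_trial_sd = 0,
                     mimicry_coupling_base = 0, mimicry_coupling_aq = 0)
  eff$emg_amplitude[, ] <- 0
  eff$emg_amplitude["happiness", "zygomaticus"] <- 4
  tr <- generate_traits(2, seed = 34)
  de <- generate_design(2, seed = 34)
  em <- generate_emg(tr, de, eff, seed = 34, raw = TRUE, subjects = 1)
  sig <- em$signal[em$signal$muscle == "zygomaticus", ]
  sig$value <- filter_rectify(sig$value[order(sig$t_ms)])
  ep <- epoch_and_bin(sig, em$markers)
  ep <- baseline_correct(ep)
  su <- summarize_emg(ep, de$stimuli)
  hz <- su$trial_avg$value[su$trial_avg$category == "happiness"]
  expect_lt(abs(mean(hz, na.rm = TRUE) - 4) / 4, 0.05)
})
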