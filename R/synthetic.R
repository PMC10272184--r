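## Synthetic-study generator: trait questionnaires, study design, recognition
## ratings and facial-EMG signals with known ground truth.

#' Target distributions for the simulated trait questionnaires
#'
#' Defaults reproduce the reference sample: social anxiety totals
#' approximately normal (mean 38.53, SD 17.53) and autistic-trait totals
#' positively skewed (mean 16.38, SD 7.34, skewness 1.05), generated
#' independently of each other.
#'
#' @param lsas_mean,lsas_sd target moments of the LSAS total (0-144).
#' @param aq_mean,aq_sd,aq_skew target moments of the AQ total (0-50).
#' @return a parameter list for [generate_traits()].
#' @export
trait_params <- function(lsas_mean = 38.53, lsas_sd = 17.53,
                         aq_mean = 16.38, aq_sd = 7.34, aq_skew = 1.05) {
  if (lsas_sd <= 0 || aq_sd <= 0)
    stop_mimicog("trait SDs must be positive", "mimicog_parameter_error")
  list(lsas = list(mean = lsas_mean, sd = lsas_sd),
       aq = list(mean = aq_mean, sd = aq_sd, skew = aq_skew))
}

## ---- calibration ----------------------------------------------------------
## Item-generating models are calibrated once (numerically, via quadrature
## over the latent trait) so that simulated item *sums* hit the target
## moments; results are cached per target set.

.calib_cache <- new.env(parent = emptyenv())

.quad_grid <- function() {
  th <- seq(-6, 6, length.out = 241L)
  w <- dnorm(th)
  list(th = th, w = w / sum(w))
}

## LSAS: 48 ordinal items 0..3 from a one-factor thresholded Gaussian copula.
## Free parameters: threshold location a (tau = a + 0:2) and loading lambda.
calibrate_lsas <- function(target_mean, target_sd) {
  key <- paste("lsas", target_mean, target_sd)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  g <- .quad_grid()
  moments <- function(a, lam) {
    tau <- a + c(0, 1, 2)
    s <- sqrt(1 - lam^2)
    q <- sapply(tau, function(t) pnorm((lam * g$th - t) / s)) # 241 x 3
    m <- rowSums(q)                       # E[item | theta]
    e2 <- q %*% c(1, 3, 5)                # E[item^2 | theta]
    v <- pmax(0, e2 - m^2)
    Em <- sum(g$w * m)
    Vm <- sum(g$w * m^2) - Em^2
    list(mean = 48 * Em, var = 48 * sum(g$w * v) + 48^2 * Vm)
  }
  obj <- function(p) {
    mo <- moments(p[1L], plogis(p[2L]) * 0.95)
    (mo$mean - target_mean)^2 + (sqrt(mo$var) - target_sd)^2
  }
  fit <- optim(c(-0.3, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  out <- list(a = fit$par[1L], lambda = plogis(fit$par[2L]) * 0.95)
  .calib_cache[[key]] <- out
  out
}

## AQ: 50 dichotomously scored items; keyed-direction probability follows a
## logistic link on a standardized log-normal latent (produces the positive
## skew of the totals). Free parameters: intercept a, slope b, latent sigma.
calibrate_aq <- function(target_mean, target_sd, target_skew) {
  key <- paste("aq", target_mean, target_sd, target_skew)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  g <- .quad_grid()
  moments <- function(a, b, sig) {
    zeta <- (exp(sig * g$th) - exp(sig^2 / 2)) /
      sqrt((exp(sig^2) - 1) * exp(sig^2))
    p <- plogis(a + b * zeta)
    mu <- 50 * sum(g$w * p)
    vv <- 50 * sum(g$w * p * (1 - p)) + 2500 * (sum(g$w * p^2) - sum(g$w * p)^2)
    dev <- 50 * p - mu
    m3 <- sum(g$w * (50 * p * (1 - p) * (1 - 2 * p) +
                       3 * 50 * p * (1 - p) * dev + dev^3))
    list(mean = mu, var = vv, skew = m3 / vv^1.5)
  }
  obj <- function(par) {
    mo <- moments(par[1L], exp(par[2L]), exp(par[3L]))
    (mo$mean - target_mean)^2 + (sqrt(mo$var) - target_sd)^2 +
      25 * (mo$skew - target_skew)^2
  }
  fit <- optim(c(qlogis(target_mean / 50), log(0.5), log(0.8)), obj,
               method = "Nelder-Mead", control = list(maxit = 1000, reltol = 1e-10))
  out <- list(a = fit$par[1L], b = exp(fit$par[2L]), sigma = exp(fit$par[3L]))
  .calib_cache[[key]] <- out
  out
}

## ---- effects --------------------------------------------------------------

#' Simulation effect structure
#'
#' Bundles every effect the generator injects, so downstream
#' parameter-recovery tests know the ground truth. Trait effects are per SD
#' of the trait total; EMG amplitudes are in (approximately) post-pipeline
#' z-units; couplings modulate the link between mimicry or confidence and
#' correctness.
#'
#' Category difficulty defaults are the log odds-ratios of the reported
#' category effects in the reference study (happiness easiest, fear hardest);
#' the per-SD trait slopes default to plausible magnitudes for a study of
#' this design (see the methods vignette). Setting every trait-linked term
#' and coupling to zero (see [sim_effects_null()]) yields trait-independent
#' data.
#'
#' @param ... named overrides of any default field.
#' @return an object of class `sim_effects` (a validated list).
#' @export
sim_effects <- function(...) {
  cat_eff <- c(anger = -0.16021, fear = -2.71810, happiness = 2.38278,
               neutral = 0.84899, sadness = -1.46102, surprise = 1.10756)
  amp <- matrix(0, 6L, 2L,
                dimnames = list(EMOTION_CATEGORIES, c("corrugator", "zygomaticus")))
  amp["anger", "corrugator"] <- 0.30
  amp["fear", "corrugator"] <- 0.10
  amp["sadness", "corrugator"] <- 0.15
  amp["happiness", "corrugator"] <- -0.30
  amp["happiness", "zygomaticus"] <- 0.40
  amp["surprise", "zygomaticus"] <- 0.05
  defaults <- list(
    accuracy_intercept = 0.65,
    category_effects = cat_eff,
    b_aq_accuracy = -0.30,
    b_aq_fear_extra = -0.45,
    b_lsas_accuracy = 0,
    b_lsas_confidence = -3.3,
    b_aq_confidence = 0,
    confidence_base = 55,
    confidence_sd = 20,
    metacog_coupling_base = 15,
    metacog_coupling_aq = -6,
    emg_amplitude = amp,
    mimicry_coupling_base = 0.5,
    mimicry_coupling_aq = -0.25,
    mimicry_trial_sd = 0.2,
    emg_noise_sd = 1,
    emg_base_level = 8,
    artifact_rate = 0.02,
    artifact_magnitude = 10,
    simplicity_means = c(anger = 45.05, fear = 50.93, happiness = 69.39,
                         neutral = 36.42, sadness = 36.19, surprise = 62.51),
    simplicity_sd = 26,
    intensity_base = 60,
    intensity_sd = 20,
    rng_seed = NULL
  )
  eff <- modifyList(defaults, list(...))
  num <- unlist(eff[setdiff(names(eff), "rng_seed")])
  if (any(!is.finite(num)))
    stop_mimicog("all effect terms must be finite", "mimicog_parameter_error")
  if (eff$artifact_rate < 0 || eff$artifact_rate > 1)
    stop_mimicog("artifact_rate must lie in [0, 1]", "mimicog_parameter_error")
  structure(eff, class = "sim_effects")
}

#' Null effect structure: no trait modulation, no mimicry/metacognitive link
#'
#' Category difficulty and mimicry amplitudes are retained; every trait slope
#' and every coupling between traits, EMG, confidence and correctness is zero,
#' so the generated data are trait-independent and confidence carries no
#' information about correctness.
#'
#' @param ... further overrides passed to [sim_effects()].
#' @export
sim_effects_null <- function(...) {
  sim_effects(b_aq_accuracy = 0, b_aq_fear_extra = 0, b_lsas_accuracy = 0,
              b_lsas_confidence = 0, b_aq_confidence = 0,
              metacog_coupling_base = 0, metacog_coupling_aq = 0,
              mimicry_coupling_base = 0, mimicry_coupling_aq = 0, ...)
}

## ---- traits ---------------------------------------------------------------

#' Generate item-level questionnaire responses for n subjects
#'
#' LSAS item responses come from a one-factor thresholded Gaussian copula
#' (24 fear + 24 avoidance items, 0-3), AQ responses from a logistic model on
#' a standardized log-normal latent (50 items, 1-4, standard key). Both
#' models are calibrated so that simulated totals hit the target moments in
#' `params`; the two traits are generated independently.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params target distribution spec from [trait_params()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with `subject_id`, 48 `lsas_*` item columns, 50 `aq_*`
#'   item columns, totals and cut-off flags.
#' @export
generate_traits <- function(n_subjects, params = trait_params(), seed = 1L) {
  if (n_subjects < 2L)
    stop_mimicog("n_subjects must be at least 2", "mimicog_parameter_error")
  cal_l <- calibrate_lsas(params$lsas$mean, params$lsas$sd)
  cal_a <- calibrate_aq(params$aq$mean, params$aq$sd, params$aq$skew)
  set.seed(child_seed(seed, "traits"))

  ## LSAS
  theta <- rnorm(n_subjects)
  s <- sqrt(1 - cal_l$lambda^2)
  x <- cal_l$lambda * theta + s * matrix(rnorm(n_subjects * 48L), n_subjects, 48L)
  tau <- cal_l$a + c(0, 1, 2)
  lsas <- (x > tau[1L]) + (x > tau[2L]) + (x > tau[3L])

  ## AQ
  w <- rnorm(n_subjects)
  zeta <- (exp(cal_a$sigma * w) - exp(cal_a$sigma^2 / 2)) /
    sqrt((exp(cal_a$sigma^2) - 1) * exp(cal_a$sigma^2))
  p <- plogis(cal_a$a + cal_a$b * zeta)
  keyed <- matrix(rbinom(n_subjects * 50L, 1L, p), n_subjects, 50L)
  u <- matrix(sample(0:1, n_subjects * 50L, replace = TRUE), n_subjects, 50L)
  key <- aq_default_key()
  agree <- matrix(rep(key, each = n_subjects), n_subjects, 50L)
  ## keyed direction = agree side for agree-keyed items, disagree side else
  aq <- ifelse(agree == (keyed == 1L), 1L + u, 3L + u)

  out <- data.frame(subject_id = seq_len(n_subjects))
  lsas_names <- c(paste0("lsas_f", 1:24), paste0("lsas_a", 1:24))
  out[lsas_names] <- as.data.frame(lsas)
  out[paste0("aq_", 1:50)] <- as.data.frame(aq)
  out$lsas_total <- score_lsas(lsas)
  out$aq_total <- score_aq(aq)
  out$lsas_above_cutoff <- out$lsas_total > 30
  out$aq_above_cutoff <- out$aq_total > 32
  attr(out, "latents") <- list(lsas_theta = theta, aq_latent = zeta)
  out
}

## ---- design ---------------------------------------------------------------

#' Generate the study design and per-subject trial schedules
#'
#' 6 expression categories x 10 identities = 60 unique stimuli. The passive
#' (EMG) task shows every stimulus twice, once per block (120 trials per
#' subject); the recognition task shows every stimulus once (60 trials), all
#' in per-subject random order.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @return an object of class `study_design`: list with `stimuli`, `passive`,
#'   `recognition` data.frames and `n_subjects`.
#' @export
generate_design <- function(n_subjects, seed = 1L) {
  if (n_subjects < 1L)
    stop_mimicog("n_subjects must be at least 1", "mimicog_parameter_error")
  stimuli <- data.frame(
    stimulus_id = paste0(rep(substr(EMOTION_CATEGORIES, 1, 3), each = 10L),
                         "_", sprintf("%02d", rep(1:10, 6L))),
    category = rep(EMOTION_CATEGORIES, each = 10L),
    identity = rep(1:10, 6L)
  )
  set.seed(child_seed(seed, "design"))
  passive <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    ord <- c(sample(stimuli$stimulus_id), sample(stimuli$stimulus_id))
    d <- data.frame(subject_id = s, trial = seq_len(120L), stimulus_id = ord)
    d$presentation <- ave(rep(1L, 120L), d$stimulus_id, FUN = cumsum)
    d
  }))
  recognition <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject_id = s, trial = seq_len(60L),
               stimulus_id = sample(stimuli$stimulus_id))
  }))
  structure(list(stimuli = stimuli, passive = passive,
                 recognition = recognition, n_subjects = n_subjects),
            class = "study_design")
}

## ---- ratings --------------------------------------------------------------

## Preferred confusions for incorrect trials (fear <-> surprise,
## sadness <-> neutral); remaining categories are drawn uniformly with lower
## weight. Rows = true category, columns = responded category.
confusion_weights <- function() {
  w <- matrix(1, 6L, 6L, dimnames = list(EMOTION_CATEGORIES, EMOTION_CATEGORIES))
  diag(w) <- 0
  w["fear", "surprise"] <- 3; w["surprise", "fear"] <- 3
  w["sadness", "neutral"] <- 3; w["neutral", "sadness"] <- 3
  w
}

#' Generate slider ratings for the recognition task
#'
#' Per trial, correctness is drawn from a logistic model in category
#' difficulty and standardized traits; the six category sliders are then
#' constructed so that the true category holds the unique maximum iff the
#' trial is correct (a confusable category wins otherwise). Confidence is
#' base + coupling * (correct - 1/2) + trait shift + noise, rounded to the
#' 11-point grid and clipped to [0, 100]; the coupling decreases with
#' autistic traits, which is what degrades metacognitive sensitivity.
#'
#' @param traits trait table from [generate_traits()].
#' @param design design from [generate_design()].
#' @param effects a [sim_effects()] object.
#' @param seed integer seed.
#' @return list with `ratings` (one row per recognition trial) and
#'   `ground_truth` (true effects, per-trial latent correctness probability,
#'   drawn correctness, standardized traits).
#' @export
generate_ratings <- function(traits, design, effects = sim_effects(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), nrow(traits) == design$n_subjects)
  set.seed(child_seed(seed, "ratings"))
  aq_z <- z_std(traits$aq_total)
  lsas_z <- z_std(traits$lsas_total)

  rec <- merge(design$recognition, design$stimuli, by = "stimulus_id", sort = FALSE)
  rec <- rec[order(rec$subject_id, rec$trial), ]
  n <- nrow(rec)
  sub <- rec$subject_id
  cat <- rec$category

  eta <- effects$accuracy_intercept + effects$category_effects[cat] +
    (effects$b_aq_accuracy + effects$b_aq_fear_extra * (cat == "fear")) * aq_z[sub] +
    effects$b_lsas_accuracy * lsas_z[sub]
  p_correct <- plogis(unname(eta))
  correct <- rbinom(n, 1L, p_correct)

  ## responded category: truth when correct, weighted confusion otherwise
  cw <- confusion_weights()
  responded <- cat
  wrong <- which(correct == 0L)
  if (length(wrong)) {
    responded[wrong] <- vapply(wrong, function(i) {
      sample(EMOTION_CATEGORIES, 1L, prob = cw[cat[i], ])
    }, character(1L))
  }

  ## slider matrix: winner gets a high grid value, the rest strictly less
  winner_val <- 10L * sample(6:10, n, replace = TRUE)
  sliders <- matrix(0L, n, 6L, dimnames = list(NULL, EMOTION_CATEGORIES))
  for (j in seq_len(6L)) {
    upper <- pmax(0L, winner_val %/% 10L - 1L)
    sliders[, j] <- 10L * floor(runif(n) * (upper + 1L))
  }
  sliders[cbind(seq_len(n), match(responded, EMOTION_CATEGORIES))] <- winner_val

  coupling <- pmax(0, effects$metacog_coupling_base +
                     effects$metacog_coupling_aq * aq_z[sub])
  conf <- effects$confidence_base + coupling * (correct - 0.5) +
    effects$b_lsas_confidence * lsas_z[sub] +
    effects$b_aq_confidence * aq_z[sub] +
    rnorm(n, 0, effects$confidence_sd)
  confidence <- snap_to_grid(conf)
  intensity <- snap_to_grid(rnorm(n, effects$intensity_base, effects$intensity_sd))
  simplicity <- snap_to_grid(rnorm(n, effects$simplicity_means[cat], effects$simplicity_sd))

  ratings <- data.frame(subject_id = sub, trial = rec$trial,
                        stimulus_id = rec$stimulus_id, true_category = cat)
  ratings[paste0("slider_", EMOTION_CATEGORIES)] <- as.data.frame(sliders)
  ratings$intensity <- intensity
  ratings$confidence <- confidence
  ratings$simplicity <- simplicity

  bad <- !apply(sapply(ratings[paste0("slider_", EMOTION_CATEGORIES)], is_on_grid), 1L, all)
  if (any(bad))
    stop_mimicog("internal consistency error: slider off the 11-point grid",
                 "mimicog_internal_error")

  list(ratings = ratings,
       ground_truth = list(effects = effects, p_correct = p_correct,
                           correct = correct, aq_z = aq_z, lsas_z = lsas_z))
}

## ---- EMG ------------------------------------------------------------------

## Dominant mimicry muscle per category (which muscle carries the
## mimicry-accuracy coupling).
dominant_muscle <- c(anger = "corrugator", fear = "corrugator",
                     happiness = "zygomaticus", neutral = NA,
                     sadness = "corrugator", surprise = "zygomaticus")

## Response-window amplitude profile over the 15 response bins: ramp over the
## first 500 ms, plateau over the last second (the analysis window).
response_profile <- function() c(seq(0.2, 1, length.out = 5L), rep(1, 10L))

## Epoch layout (ms) used by both the generator and the preprocessing:
## fixation 1000 | baseline 500 | response 1500 | post 1500, then ITI.
EPOCH_BINS <- c(fixation = 10L, baseline = 5L, response = 15L, post = 15L)
TRIAL_MS <- 5000L   # fixation + stimulus + post + short synthetic ITI

#' Generate facial-EMG data with ground-truth artifact masks
#'
#' Two modes share one trial-level amplitude model: per passive trial and
#' muscle, amplitude = category/muscle mimicry amplitude + trial jitter
#' (+ mimicry-accuracy coupling times (correct - 1/2) on the category's
#' dominant muscle when `ratings` are supplied, tying mimicry strength to
#' later recognition of the same stimulus).
#'
#' * `raw = TRUE`: a 1000 Hz two-channel recording per subject. The signal is
#'   amplitude-modulated broadband noise, scaled so that the
#'   filtered-and-rectified 100-ms bin means equal `emg_base_level` plus the
#'   injected amplitude. Artifacts are large square transients spanning one
#'   100-ms bin.
#' * `raw = FALSE` (fast path): rectified bin means are emitted directly in
#'   the same epoch layout, skipping sample-level synthesis. Statistically
#'   matched to the raw path after [filter_rectify()] + [epoch_and_bin()];
#'   used for large parameter-recovery simulations where sample-level
#'   synthesis is computationally out of reach.
#'
#' Artifact bins (probability `artifact_rate` per interest bin) receive a
#' `artifact_magnitude` * noise-SD offset; the mask is returned as ground
#' truth.
#'
#' @param traits,design,effects,seed as in [generate_ratings()].
#' @param ratings optional result of [generate_ratings()] (enables the
#'   mimicry-accuracy coupling).
#' @param raw generate the sample-level signal (default FALSE).
#' @param subjects optional subset of subject ids (raw mode can be large).
#' @return an object of class `sim_emg`: list with either `signal` (+
#'   `markers`, raw mode) or `epochs` (fast path), `fs`, and `ground_truth`
#'   (artifact mask, per-trial amplitudes, effects).
#' @export
generate_emg <- function(traits, design, effects = sim_effects(), seed = 1L,
                         ratings = NULL, raw = FALSE, subjects = NULL) {
  stopifnot(inherits(design, "study_design"))
  set.seed(child_seed(seed, "emg"))
  aq_z <- z_std(traits$aq_total)

  pv <- merge(design$passive, design$stimuli, by = "stimulus_id", sort = FALSE)
  pv <- pv[order(pv$subject_id, pv$trial), ]
  if (!is.null(subjects)) pv <- pv[pv$subject_id %in% subjects, ]
  n_tr <- nrow(pv)

  ## correctness of the matching recognition trial, if ratings are supplied
  corr <- rep(NA_real_, n_tr)
  if (!is.null(ratings)) {
    r <- ratings$ratings
    acc <- score_accuracy(r)
    key <- paste(r$subject_id, r$stimulus_id)
    corr <- acc[match(paste(pv$subject_id, pv$stimulus_id), key)]
  }

  mask_list <- list()
  amp_tab <- NULL
  muscles <- c("corrugator", "zygomaticus")
  amp <- matrix(NA_real_, n_tr, 2L, dimnames = list(NULL, muscles))
  for (m in muscles) {
    a <- effects$emg_amplitude[pv$category, m] +
      rnorm(n_tr, 0, effects$mimicry_trial_sd)
    cpl <- effects$mimicry_coupling_base + effects$mimicry_coupling_aq * aq_z[pv$subject_id]
    dom <- dominant_muscle[pv$category] == m
    use <- !is.na(corr) & !is.na(dom) & dom
    a[use] <- a[use] + (cpl[use] * (corr[use] - 0.5))
    amp[, m] <- a
  }

  ## ground-truth artifact mask over the 20 interest bins per trial x muscle
  mask <- array(runif(n_tr * 2L * 20L) < effects$artifact_rate,
                dim = c(n_tr, 2L, 20L), dimnames = list(NULL, muscles, NULL))

  amp_tab <- data.frame(subject_id = rep(pv$subject_id, 2L),
                        trial = rep(pv$trial, 2L),
                        stimulus_id = rep(pv$stimulus_id, 2L),
                        muscle = rep(muscles, each = n_tr),
                        amplitude = c(amp[, 1L], amp[, 2L]))
  mask_df <- do.call(rbind, lapply(seq_along(muscles), function(mi) {
    idx <- which(mask[, mi, ], arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(subject_id = pv$subject_id[idx[, 1L]], trial = pv$trial[idx[, 1L]],
               muscle = muscles[mi], interest_bin = idx[, 2L])
  }))
  if (is.null(mask_df))
    mask_df <- data.frame(subject_id = integer(), trial = integer(),
                          muscle = character(), interest_bin = integer())
  gt <- list(effects = effects, artifact_mask = mask_df, amplitudes = amp_tab)

  sigma <- effects$emg_noise_sd
  base <- effects$emg_base_level
  prof <- response_profile()

  if (!raw) {
    nb <- sum(EPOCH_BINS)   # 45 bins per trial
    epoch_lab <- rep(names(EPOCH_BINS), EPOCH_BINS)
    bin_lab <- unlist(lapply(EPOCH_BINS, seq_len), use.names = FALSE)
    prof_full <- c(rep(0, 10L), rep(0, 5L), prof, rep(0, 15L))
    rows_per_muscle <- n_tr * nb
    ep <- data.frame(
      subject_id = rep(rep(pv$subject_id, each = nb), 2L),
      muscle = rep(muscles, each = rows_per_muscle),
      trial = rep(rep(pv$trial, each = nb), 2L),
      stimulus_id = rep(rep(pv$stimulus_id, each = nb), 2L),
      presentation = rep(rep(pv$presentation, each = nb), 2L),
      category = rep(rep(pv$category, each = nb), 2L),
      epoch = rep(rep(epoch_lab, n_tr), 2L),
      bin = rep(rep(bin_lab, n_tr), 2L)
    )
    val <- base + rnorm(nrow(ep), 0, sigma) +
      rep(prof_full, 2L * n_tr) * c(rep(amp[, 1L], each = nb), rep(amp[, 2L], each = nb))
    ## inject artifacts at masked interest bins
    interest <- ep$epoch %in% c("baseline", "response")
    ib <- integer(nrow(ep))
    ib[interest] <- ifelse(ep$epoch[interest] == "baseline",
                           ep$bin[interest], 5L + ep$bin[interest])
    tr_idx <- rep(rep(seq_len(n_tr), each = nb), 2L)
    mu_idx <- rep(1:2, each = rows_per_muscle)
    hit <- interest & mask[cbind(tr_idx, mu_idx, pmax(ib, 1L))]
    val[hit] <- val[hit] + effects$artifact_magnitude * sigma
    ep$value <- val
    ep$excluded <- FALSE
    epochs <- structure(ep, class = c("emg_epochs", "data.frame"), fs = 1000)
    return(structure(list(epochs = epochs, fs = 1000, ground_truth = gt),
                     class = "sim_emg"))
  }

  ## raw mode: amplitude-modulated broadband noise at 1000 Hz
  kappa <- filter_rectified_mean_scale()
  subjects_used <- unique(pv$subject_id)
  sig_list <- vector("list", length(subjects_used) * 2L)
  markers <- NULL
  li <- 0L
  for (s in subjects_used) {
    rows <- which(pv$subject_id == s)
    n_s <- length(rows)
    total <- n_s * TRIAL_MS
    onset <- (seq_len(n_s) - 1L) * TRIAL_MS + 1000L
    markers <- rbind(markers, data.frame(
      subject_id = s, trial = pv$trial[rows], stimulus_id = pv$stimulus_id[rows],
      presentation = pv$presentation[rows], category = pv$category[rows],
      onset_ms = onset))
    ## per-ms level profile (rectified-mean units)
    for (mi in 1:2) {
      lev <- rep(base, total)
      for (k in seq_len(n_s)) {
        t0 <- onset[k]
        resp <- t0 + 500L
        lev[(resp + 1L):(resp + 1500L)] <- base +
          amp[rows[k], mi] * rep(prof, each = 100L)
      }
      x <- rnorm(total, 0, 1) * (lev / kappa)
      ## artifact transients: one full bin gets a large offset
      hit <- which(mask[rows, mi, ], arr.ind = TRUE)
      if (length(hit)) {
        for (h in seq_len(nrow(hit))) {
          k <- hit[h, 1L]; b <- hit[h, 2L]
          start <- onset[k] + (b - 1L) * 100L  # interest bins begin at stimulus onset
          x[(start + 1L):(start + 100L)] <- x[(start + 1L):(start + 100L)] +
            effects$artifact_magnitude * base
        }
      }
      li <- li + 1L
      sig_list[[li]] <- data.frame(subject_id = s, muscle = muscles[mi],
                                   t_ms = seq_len(total) - 1L, value = x)
    }
  }
  signal <- do.call(rbind, sig_list)
  structure(list(signal = signal, markers = markers, fs = 1000,
                 ground_truth = gt), class = "sim_emg")
}

#' Simulate a complete study
#'
#' Fans one master seed out to the trait, design, rating and EMG stages and
#' returns all stage outputs plus ground truth.
#'
#' @param n_subjects number of subjects.
#' @param effects a [sim_effects()] object.
#' @param seed master integer seed.
#' @param params trait targets from [trait_params()].
#' @param emg one of `"none"`, `"epochs"` (fast path) or `"raw"`.
#' @return list with `traits`, `design`, `ratings`, `emg` (or NULL) and
#'   `ground_truth`.
#' @export
simulate_study <- function(n_subjects, effects = sim_effects(), seed = 1L,
                           params = trait_params(),
                           emg = c("epochs", "raw", "none")) {
  emg <- match.arg(emg)
  traits <- generate_traits(n_subjects, params, seed)
  design <- generate_design(n_subjects, seed)
  ratings <- generate_ratings(traits, design, effects, seed)
  emg_out <- if (emg == "none") NULL else
    generate_emg(traits, design, effects, seed, ratings = ratings,
                 raw = (emg == "raw"))
  list(traits = traits, design = design, ratings = ratings, emg = emg_out,
       ground_truth = ratings$ground_truth)
}
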