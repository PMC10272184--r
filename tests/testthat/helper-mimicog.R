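## Fixture builders shared across test files.

## Build an emg_epochs frame from a trials x 45 value matrix (10 fixation,
## 5 baseline, 15 response, 15 post bins per trial) for one subject-muscle.
make_epochs <- function(values, subject_id = 1L, muscle = "corrugator",
                        stimulus_id = NULL, presentation = 1L,
                        category = "anger") {
  nb <- c(fixation = 10L, baseline = 5L, response = 15L, post = 15L)
  n_tr <- nrow(values)
  if (is.null(stimulus_id)) stimulus_id <- paste0("stim_", seq_len(n_tr))
  ep <- data.frame(
    subject_id = subject_id, muscle = muscle,
    trial = rep(seq_len(n_tr), each = sum(nb)),
    stimulus_id = rep(stimulus_id, each = sum(nb)),
    presentation = rep(presentation, length.out = n_tr)[rep(seq_len(n_tr), each = sum(nb))],
    category = rep(category, length.out = n_tr)[rep(seq_len(n_tr), each = sum(nb))],
    epoch = rep(rep(names(nb), nb), n_tr),
    bin = rep(unlist(lapply(nb, seq_len), use.names = FALSE), n_tr),
    value = as.vector(t(values)), excluded = FALSE)
  structure(ep, class = c("emg_epochs", "data.frame"), fs = 1000)
}

## One-row ratings table from named slider values.
make_rating <- function(true_category, ..., confidence = 50) {
  sliders <- setNames(rep(0L, 6L),
                      c("anger", "fear", "happiness", "neutral", "sadness", "surprise"))
  ov <- list(...)
  sliders[names(ov)] <- unlist(ov)
  out <- data.frame(subject_id = 1L, stimulus_id = "s1", true_category = true_category)
  out[paste0("slider_", names(sliders))] <- as.list(as.integer(sliders))
  out$confidence <- confidence
  out
}

## Random on-grid slider table for property tests.
random_ratings <- function(n, seed) {
  set.seed(seed)
  cats <- c("anger", "fear", "happiness", "neutral", "sadness", "surprise")
  out <- data.frame(subject_id = 1L, stimulus_id = paste0("s", seq_len(n)),
                    true_category = sample(cats, n, replace = TRUE))
  for (cc in cats) out[[paste0("slider_", cc)]] <- 10L * sample(0:10, n, replace = TRUE)
  out$confidence <- 10L * sample(0:10, n, replace = TRUE)
  out
}

## Brute-force accuracy oracle: enumerate all maxima explicitly.
oracle_accuracy <- function(ratings) {
  cats <- c("anger", "fear", "happiness", "neutral", "sadness", "surprise")
  vapply(seq_len(nrow(ratings)), function(i) {
    v <- as.numeric(ratings[i, paste0("slider_", cats)])
    at_max <- cats[v == max(v)]
    if (length(at_max) > 1L) return(NA_real_)
    as.numeric(at_max == ratings$true_category[i])
  }, numeric(1L))
}

## Pairwise rank oracle for AUROC2: P(conf_c > conf_i) + 0.5 P(equal).
oracle_auroc2 <- function(confidence, correct) {
  cc <- confidence[correct == 1]; ci <- confidence[correct == 0]
  d <- outer(cc, ci, "-")
  mean((d > 0) + 0.5 * (d == 0))
}

## Brute-force artifact flags implementing the 3.5 SD dual-reference rule
## directly on a trials x 20 interest matrix.
oracle_artifact_flags <- function(M, z = 3.5) {
  FL <- matrix(FALSE, nrow(M), 20L)
  mark <- function(vals, sel = TRUE) {
    mu <- mean(vals, na.rm = TRUE); s <- sd(as.vector(vals), na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(vals & FALSE)
    !is.na(vals) & abs(vals - mu) > z * s
  }
  FL <- FL | mark(M)
  D <- M[, -1, drop = FALSE] - M[, -20, drop = FALSE]
  FL[, -1] <- FL[, -1] | mark(D)
  for (p in 1:5) FL[, p] <- FL[, p] | mark(M[, p, drop = FALSE])
  for (p in 2:5) FL[, p] <- FL[, p] | mark(M[, p, drop = FALSE] - M[, p - 1, drop = FALSE])
  FL
}

## Extract the trials x 20 interest matrix and flag matrix from an epochs
## frame (single subject-muscle).
epochs_interest <- function(ep, what = "value") {
  int <- ep$epoch %in% c("baseline", "response")
  col <- ifelse(ep$epoch[int] == "baseline", ep$bin[int], 5L + ep$bin[int])
  trials <- sort(unique(ep$trial[int]))
  M <- matrix(NA, length(trials), 20L)
  M[cbind(match(ep$trial[int], trials), col)] <- ep[[what]][int]
  M
}
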