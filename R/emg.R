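## Facial-EMG preprocessing: band-pass + notch filtering, rectification,
## 100-ms binning, distribution-based artifact rejection, baseline
## correction, within-subject z-scoring and trial/category averaging.

## Zero-phase amplitude response applied to the data: squared Butterworth
## band-pass magnitude times squared notch magnitude (the magnitude response
## of a forward-backward filter). The upper band edge is capped at
## fs/2 - 1 Hz (500 Hz equals Nyquist at fs = 1000).
.filter_response <- function(f, fs = 1000, band = c(28, 500), notch = 50,
                             order = 4, notch_q = 35) {
  f_lo <- band[1L]
  f_hi <- min(band[2L], fs / 2 - 1)
  hp2 <- ifelse(f <= 0, 0, 1 / (1 + (f_lo / pmax(f, 1e-12))^(2 * order)))
  lp2 <- 1 / (1 + (f / f_hi)^(2 * order))
  resp <- hp2 * lp2
  if (!is.null(notch) && notch > 0) {
    bw <- notch / notch_q
    num <- (f^2 - notch^2)^2
    resp <- resp * num / (num + (bw * f)^2)
  }
  resp
}

## Expected rectified mean of unit-variance white noise after the filter;
## used by the raw-signal generator to express amplitudes in
## rectified-bin-mean units.
filter_rectified_mean_scale <- function(fs = 1000, band = c(28, 500),
                                        notch = 50, order = 4) {
  N <- 4096L
  f <- (seq_len(N) - 1L) / N * fs
  fk <- pmin(f, fs - f)
  r <- .filter_response(fk, fs, band, notch, order)
  sqrt(2 / pi) * sqrt(mean(r^2))
}

#' Condition a raw EMG signal: band-pass, notch, rectify
#'
#' Applies a zero-phase 28-500 Hz Butterworth band-pass (order 4) and a 50 Hz
#' notch in the frequency domain (equivalent to forward-backward filtering),
#' then full-wave rectifies. The upper edge is implemented at `fs/2 - 1` Hz
#' because 500 Hz is the Nyquist frequency at the nominal 1000 Hz sampling
#' rate.
#'
#' @param x numeric signal, finite values.
#' @param fs sampling rate; must be 1000 Hz unless `allow_fs_override`.
#' @param band pass-band edges in Hz.
#' @param notch notch frequency in Hz (`NULL` disables).
#' @param order Butterworth order.
#' @param allow_fs_override permit a non-1000 Hz rate.
#' @return the conditioned (non-negative) signal.
#' @export
filter_rectify <- function(x, fs = 1000, band = c(28, 500), notch = 50,
                           order = 4, allow_fs_override = FALSE) {
  if (fs != 1000 && !allow_fs_override)
    stop_mimicog("sampling rate must be 1000 Hz (set allow_fs_override to force)",
                 "mimicog_parameter_error")
  if (!all(is.finite(x)))
    stop_mimicog("signal contains non-finite samples", "mimicog_validation_error")
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  fk <- pmin(f, fs - f)
  r <- .filter_response(fk, fs, band, notch, order)
  y <- Re(fft(fft(x) * r, inverse = TRUE)) / n
  abs(y)
}

#' Epoch a conditioned signal into 100-ms bins
#'
#' Per trial: 10 fixation bins (1 s before stimulus onset), 5 baseline bins
#' (first 500 ms of the stimulus, neutral expression), 15 response bins (the
#' following 1500 ms) and 15 post-stimulus bins. Each bin is the arithmetic
#' mean of its 100 consecutive 1-ms samples. Trials that do not fit inside
#' the recording are flagged `excluded` with `NA` bins.
#'
#' @param signal data.frame with `subject_id`, `muscle`, `t_ms`, `value`
#'   (1000 Hz, `t_ms` starting at 0 per subject/muscle).
#' @param markers data.frame with `subject_id`, `trial`, `stimulus_id`,
#'   `onset_ms` (stimulus onset) and optionally `presentation`, `category`.
#' @param fs sampling rate (1000).
#' @return an `emg_epochs` data.frame (long, one row per bin).
#' @export
epoch_and_bin <- function(signal, markers, fs = 1000) {
  if (fs != 1000)
    stop_mimicog("epoching assumes 1000 Hz", "mimicog_parameter_error")
  nb <- sum(EPOCH_BINS)
  epoch_lab <- rep(names(EPOCH_BINS), EPOCH_BINS)
  bin_lab <- unlist(lapply(EPOCH_BINS, seq_len), use.names = FALSE)
  out <- list(); oi <- 0L
  for (grp in split(signal, list(signal$subject_id, signal$muscle), drop = TRUE)) {
    s <- grp$subject_id[1L]; mu <- as.character(grp$muscle[1L])
    v <- grp$value[order(grp$t_ms)]
    mk <- markers[markers$subject_id == s, , drop = FALSE]
    if (any(diff(sort(mk$onset_ms)) < 4500))   # epoch windows span [-1000, +3500) ms
      stop_mimicog("marker overlap: trial windows collide", "mimicog_design_error")
    for (k in seq_len(nrow(mk))) {
      onset <- mk$onset_ms[k]
      lo <- onset - 1000L; hi <- onset + 3500L
      excluded <- lo < 0L || hi > length(v)
      vals <- if (excluded) rep(NA_real_, nb) else
        colMeans(matrix(v[(lo + 1L):hi], nrow = 100L))
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        subject_id = s, muscle = mu, trial = mk$trial[k],
        stimulus_id = mk$stimulus_id[k],
        presentation = mk$presentation[k] %||% NA_integer_,
        category = mk$category[k] %||% NA_character_,
        epoch = epoch_lab, bin = bin_lab, value = vals, excluded = excluded)
    }
  }
  ep <- do.call(rbind, out)
  structure(ep, class = c("emg_epochs", "data.frame"), fs = fs)
}

## trials x 20 "interest" matrix (5 baseline + 15 response bins) for one
## subject-muscle group (row indices `gidx` of `epochs`), plus the row
## indices back into the epochs frame.
.interest_matrix_idx <- function(epochs, gidx) {
  ep_epoch <- epochs$epoch[gidx]
  int <- ep_epoch == "baseline" | ep_epoch == "response"
  idx <- gidx[int]
  col <- ifelse(ep_epoch[int] == "baseline", epochs$bin[idx], 5L + epochs$bin[idx])
  trial <- epochs$trial[idx]
  trials <- sort(unique(trial))
  row <- match(trial, trials)
  M <- matrix(NA_real_, length(trials), 20L)
  M[cbind(row, col)] <- epochs$value[idx]
  list(M = M, trials = trials, idx = idx, row = row, col = col)
}

#' Distribution-based artifact detection
#'
#' For each subject and muscle, a time bin of interest (5 baseline + 15
#' response bins per trial) is flagged when it deviates more than
#' `z_threshold` SDs from the reference mean, on either the absolute bin
#' values or the differences between subsequent bins, under two reference
#' distributions: (1) all interest bins of that subject-muscle pooled across
#' trials, and (2) the across-trial distribution of baseline bins at the same
#' position. A trial is excluded entirely when strictly more than 50% of its
#' 20 interest bins (i.e. >= 11) or of its 5 baseline bins (>= 3) are
#' flagged; otherwise flagged bins are set missing. Zero-SD reference
#' distributions flag nothing.
#'
#' @param epochs an `emg_epochs` frame.
#' @param z_threshold SD criterion (default 3.5).
#' @param min_trials minimum trials per subject-muscle for stable reference
#'   distributions.
#' @return the epochs with `flagged` updated, flagged values set `NA`, and
#'   `excluded` set for rejected trials.
#' @export
detect_artifacts <- function(epochs, z_threshold = 3.5, min_trials = 10L) {
  ## accumulate per-bin results in plain vectors; a single write-back at the
  ## end avoids copying the (potentially multi-million-row) frame per group
  flag_all <- logical(nrow(epochs))
  value_all <- epochs$value
  excl_all <- epochs$excluded
  groups <- split(seq_len(nrow(epochs)),
                  list(epochs$subject_id, epochs$muscle), drop = TRUE)
  for (gidx in groups) {
    im <- .interest_matrix_idx(epochs, gidx)
    M <- im$M
    if (nrow(M) < min_trials)
      warning("fewer than ", min_trials,
              " trials for a subject-muscle; artifact references may be unstable")
    FL <- matrix(FALSE, nrow(M), 20L)
    flag_from <- function(vals, mu, s) {
      if (!is.finite(s) || s == 0) return(matrix(FALSE, nrow(vals), ncol(vals)))
      !is.na(vals) & abs(vals - mu) > z_threshold * s
    }
    ## (1a) pooled absolute values
    FL <- FL | flag_from(M, mean(M, na.rm = TRUE), sd(as.vector(M), na.rm = TRUE))
    ## (1b) pooled successive differences (first bin has no difference)
    D <- M[, -1L, drop = FALSE] - M[, -20L, drop = FALSE]
    FL[, -1L] <- FL[, -1L] |
      flag_from(D, mean(D, na.rm = TRUE), sd(as.vector(D), na.rm = TRUE))
    ## (2a) baseline bins, same position across trials
    for (p in 1:5) {
      colv <- M[, p, drop = FALSE]
      FL[, p] <- FL[, p] | flag_from(colv, mean(colv, na.rm = TRUE),
                                     sd(colv, na.rm = TRUE))[, 1L]
    }
    ## (2b) baseline successive differences, same position across trials
    for (p in 2:5) {
      dv <- M[, p, drop = FALSE] - M[, p - 1L, drop = FALSE]
      FL[, p] <- FL[, p] | flag_from(dv, mean(dv, na.rm = TRUE),
                                     sd(dv, na.rm = TRUE))[, 1L]
    }
    excl <- rowSums(FL) >= 11L | rowSums(FL[, 1:5, drop = FALSE]) >= 3L
    ## write back through the interest-bin index
    bin_flag <- FL[cbind(im$row, im$col)]
    bin_excl <- excl[im$row]
    rows <- im$idx
    flag_all[rows] <- bin_flag
    value_all[rows[bin_flag | bin_excl]] <- NA_real_
    if (any(bin_excl)) {
      excl_trials <- im$trials[excl]
      excl_all[gidx[epochs$trial[gidx] %in% excl_trials]] <- TRUE
    }
  }
  epochs$flagged <- flag_all
  epochs$value <- value_all
  epochs$excluded <- excl_all
  epochs
}

#' Baseline-correct response bins
#'
#' Subtracts each trial's mean baseline activity (missing-aware) from its 15
#' response bins; baseline bins themselves are left unchanged. Trials whose
#' five baseline bins are all missing are excluded.
#'
#' @param epochs an `emg_epochs` frame (after artifact screening).
#' @return the epochs with corrected response-bin values.
#' @export
baseline_correct <- function(epochs) {
  g <- group_id(epochs$subject_id, epochs$muscle, epochs$trial)
  bl <- epochs$epoch == "baseline"
  bmean <- group_mean(epochs$value[bl], g[bl])
  bm <- bmean[match(g, sort(unique(g[bl])))]
  resp <- epochs$epoch == "response"
  epochs$value[resp] <- epochs$value[resp] - bm[resp]
  dead <- !is.finite(bm)   # all-baseline-missing trials
  if (any(dead & resp)) {
    epochs$value[dead & resp] <- NA_real_
    epochs$excluded[dead] <- TRUE
  }
  epochs
}

#' Z-score corrected response bins per subject and muscle
#'
#' Standardizes the pooled non-missing baseline-corrected response bins of
#' each subject-muscle to mean 0, SD 1 (sample SD). Groups with fewer than
#' two values or zero variance are set missing with a warning.
#'
#' @param epochs an `emg_epochs` frame after [baseline_correct()].
#' @return the epochs with z-scored response-bin values.
#' @export
zscore_subject_muscle <- function(epochs) {
  resp <- which(epochs$epoch == "response")
  key <- interaction(epochs$subject_id[resp], epochs$muscle[resp], drop = TRUE)
  v <- epochs$value[resp]
  mu <- as.numeric(tapply(v, key, function(x) mean(x, na.rm = TRUE)))
  sdv <- as.numeric(tapply(v, key, function(x) sd(x[!is.na(x)])))
  n_ok <- as.numeric(tapply(!is.na(v), key, sum))
  bad <- !is.finite(sdv) | sdv == 0 | n_ok < 2
  if (any(bad))
    warning("zero variance or too few values for ",
            paste(levels(key)[bad], collapse = ", "), "; set missing")
  ki <- as.integer(key)
  z <- (v - mu[ki]) / sdv[ki]
  z[bad[ki]] <- NA_real_
  epochs$value[resp] <- z
  epochs
}

#' Trial- and category-averaged EMG summaries
#'
#' Trial level: missing-aware mean of the last second of the response window
#' (response bins 6-15). Trial-averaged: mean over the available
#' presentations of each stimulus. Category-averaged: mean over a category's
#' available trial-averaged values. Cells with no available data are `NA`.
#'
#' @param epochs a z-scored `emg_epochs` frame.
#' @param stimuli optional stimulus table (`stimulus_id`, `category`) used
#'   when the epochs carry no category column.
#' @return list of data.frames `trial_level`, `trial_avg`, `cat_avg`.
#' @export
summarize_emg <- function(epochs, stimuli = NULL) {
  if (all(is.na(epochs$category)) && !is.null(stimuli))
    epochs$category <- stimuli$category[match(epochs$stimulus_id, stimuli$stimulus_id)]
  last <- which(epochs$epoch == "response" & epochs$bin >= 6L)

  g1 <- group_id(epochs$subject_id[last], epochs$muscle[last], epochs$trial[last])
  rep1 <- last[match(sort(unique(g1)), g1)]
  tl <- data.frame(subject_id = epochs$subject_id[rep1], muscle = epochs$muscle[rep1],
                   trial = epochs$trial[rep1], stimulus_id = epochs$stimulus_id[rep1],
                   presentation = epochs$presentation[rep1],
                   category = epochs$category[rep1],
                   value = group_mean(epochs$value[last], g1))

  g2 <- group_id(tl$subject_id, tl$muscle, tl$stimulus_id)
  rep2 <- match(sort(unique(g2)), g2)
  ta <- data.frame(subject_id = tl$subject_id[rep2], muscle = tl$muscle[rep2],
                   stimulus_id = tl$stimulus_id[rep2], category = tl$category[rep2],
                   value = group_mean(tl$value, g2))

  g3 <- group_id(ta$subject_id, ta$muscle, ta$category)
  rep3 <- match(sort(unique(g3)), g3)
  ca <- data.frame(subject_id = ta$subject_id[rep3], muscle = ta$muscle[rep3],
                   category = ta$category[rep3],
                   value = group_mean(ta$value, g3))

  list(trial_level = tl, trial_avg = ta, cat_avg = ca)
}

#' Run the full EMG preprocessing chain
#'
#' Raw input: filter + rectify per subject-muscle recording, epoch into
#' 100-ms bins, artifact screening, baseline correction, z-scoring and
#' summarizing. Bin-level input (the generator's fast path) skips the first
#' two steps.
#'
#' @param emg a `sim_emg` object, or a list with `signal` + `markers`
#'   (raw) or `epochs` (binned).
#' @param stimuli optional stimulus table for category assignment.
#' @param z_threshold artifact SD criterion.
#' @param band,notch,order filter settings for raw input.
#' @param zscore apply the per-subject z-scoring step (default TRUE; disable
#'   to keep summaries in rectified amplitude units).
#' @return list with `epochs` (screened, corrected, z-scored) and the three
#'   summary tables of [summarize_emg()].
#' @export
preprocess_emg <- function(emg, stimuli = NULL, z_threshold = 3.5,
                           band = c(28, 500), notch = 50, order = 4,
                           zscore = TRUE) {
  if (!is.null(emg$epochs)) {
    epochs <- emg$epochs
  } else {
    sig <- emg$signal
    parts <- split(sig, list(sig$subject_id, sig$muscle), drop = TRUE)
    sig <- do.call(rbind, lapply(parts, function(g) {
      g$value <- filter_rectify(g$value[order(g$t_ms)], fs = emg$fs %||% 1000,
                                band = band, notch = notch, order = order)
      g
    }))
    epochs <- epoch_and_bin(sig, emg$markers, fs = emg$fs %||% 1000)
  }
  epochs <- detect_artifacts(epochs, z_threshold = z_threshold)
  epochs <- baseline_correct(epochs)
  if (zscore) epochs <- zscore_subject_muscle(epochs)
  c(list(epochs = epochs), summarize_emg(epochs, stimuli))
}
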