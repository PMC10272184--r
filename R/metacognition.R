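## Type-2 ROC metacognitive sensitivity and its relation to traits.

#' Type-2 ROC curve and AUROC2 for one subject
#'
#' Every interior confidence criterion `c` in 10, 20, ..., 100 splits trials
#' into low (`conf < c`) and high (`conf >= c`) confidence. Hits are
#' P(high confidence | correct), false alarms P(high confidence | incorrect).
#' The ten resulting points plus the fixed anchors (0,0) and (1,1) form the
#' type-2 ROC curve; its trapezoidal area is the metacognitive sensitivity
#' index AUROC2 (0.5 = confidence carries no information about correctness).
#'
#' @param confidence per-trial confidence on the grid 0, 10, ..., 100.
#' @param correct per-trial correctness (0/1); discounted trials must be
#'   removed upstream.
#' @return object of class `metacog`: list with `roc_points` (data.frame
#'   `fa`, `hit`, ordered), `auroc2`, `n_correct`, `n_incorrect`.
#' @export
type2_roc <- function(confidence, correct) {
  keep <- !is.na(confidence) & !is.na(correct)
  confidence <- confidence[keep]; correct <- correct[keep]
  if (!all(is_on_grid(confidence)))
    stop_mimicog("confidence must lie on the grid 0, 10, ..., 100",
                 "mimicog_validation_error")
  if (!all(correct %in% c(0, 1)))
    stop_mimicog("correct must be 0/1", "mimicog_validation_error")
  n_c <- sum(correct == 1); n_i <- sum(correct == 0)
  if (n_c == 0L || n_i == 0L)
    stop_mimicog("AUROC2 undefined: need at least one correct and one incorrect trial",
                 "mimicog_undefined_error")
  crit <- seq(10L, 100L, by = 10L)
  hit <- vapply(crit, function(cc) mean(confidence[correct == 1] >= cc), numeric(1L))
  fa <- vapply(crit, function(cc) mean(confidence[correct == 0] >= cc), numeric(1L))
  pts <- data.frame(fa = c(1, fa, 0), hit = c(1, hit, 0))
  pts <- pts[order(pts$fa, pts$hit), ]
  auc <- sum(diff(pts$fa) * (head(pts$hit, -1L) + pts$hit[-1L]) / 2)
  structure(list(roc_points = pts, auroc2 = auc,
                 n_correct = n_c, n_incorrect = n_i),
            class = "metacog")
}

#' @export
print.metacog <- function(x, ...) {
  cat(sprintf("AUROC2 = %.3f (%d correct, %d incorrect trials)\n",
              x$auroc2, x$n_correct, x$n_incorrect))
  invisible(x)
}

#' Per-subject metacognitive sensitivity for a scored ratings table
#'
#' Discounted trials are excluded; subjects with no correct or no incorrect
#' trials get `NA` with a warning.
#'
#' @param scored output of [score_ratings()] (needs `subject_id`,
#'   `confidence`, `correct`).
#' @return data.frame: `subject_id`, `auroc2`, `n_correct`, `n_incorrect`.
#' @export
compute_metacognition <- function(scored) {
  res <- lapply(split(scored, scored$subject_id), function(d) {
    d <- d[!is.na(d$correct), ]
    r <- tryCatch(type2_roc(d$confidence, d$correct),
                  mimicog_undefined_error = function(e) NULL)
    data.frame(subject_id = d$subject_id[1L],
               auroc2 = if (is.null(r)) NA_real_ else r$auroc2,
               n_correct = sum(d$correct == 1), n_incorrect = sum(d$correct == 0))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (anyNA(out$auroc2))
    warning("AUROC2 undefined for ", sum(is.na(out$auroc2)), " subject(s)")
  out
}

#' Bivariate outlier screening by Mahalanobis distance
#'
#' Squared Mahalanobis distance from the bivariate mean under the sample
#' covariance; pairs whose distance exceeds the chi-square(df = 2) quantile at
#' `1 - alpha_cut` are excluded.
#'
#' @param x,y numeric vectors (e.g. trait total and AUROC2), length >= 5.
#' @param alpha_cut tail probability of the chi-square cut (default 0.001).
#' @return list with `retained` and `excluded` index vectors and `d2`.
#' @export
mahalanobis_exclude <- function(x, y, alpha_cut = 0.001) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 5L)
    stop_mimicog("need at least 5 complete pairs", "mimicog_validation_error")
  m <- cbind(x, y)[keep, ]
  S <- var(m)
  if (!is.finite(determinant(S)$modulus) || abs(det(S)) < 1e-12 * prod(diag(S) + 1e-30))
    stop_mimicog("singular covariance; Mahalanobis distance undefined",
                 "mimicog_degenerate_error")
  d2_all <- rep(NA_real_, length(x))
  d2_all[keep] <- mahalanobis(m, colMeans(m), S)
  cut <- qchisq(1 - alpha_cut, df = 2)
  excluded <- which(!is.na(d2_all) & d2_all > cut)
  retained <- which(!is.na(d2_all) & d2_all <= cut)
  list(retained = retained, excluded = excluded, d2 = d2_all, cutoff = cut)
}

#' Correlation test with explicit t approximation
#'
#' Pearson: `t = r * sqrt(n-2) / sqrt(1-r^2)` with `df = n - 2`, two-sided p.
#' Spearman: rank correlation with the same t approximation.
#'
#' @param x,y numeric vectors, n >= 3, no missing values.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `statistic`, `df`, `p.value`, `method`, `n`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y))
    stop_mimicog("missing values not allowed", "mimicog_validation_error")
  n <- length(x)
  if (n < 3L) stop_mimicog("need at least 3 pairs", "mimicog_validation_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_mimicog("zero variance; correlation undefined", "mimicog_degenerate_error")
  r <- if (method == "pearson") cor(x, y) else cor(rank(x), rank(y))
  tt <- r * sqrt(n - 2) / sqrt(max(1e-300, 1 - r^2))
  list(estimate = r, statistic = tt, df = n - 2L,
       p.value = 2 * pt(-abs(tt), n - 2L), method = method, n = n)
}

#' t statistic of a correlation coefficient
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, the statistic used by
#' [correlation_test()]; exposed so printed correlations can be re-checked
#' from their r and n alone.
#'
#' @param r correlation coefficient.
#' @param n number of pairs.
#' @export
cor_t_stat <- function(r, n) r * sqrt(n - 2) / sqrt(1 - r^2)

#' Trait-metacognition correlation with outlier screening
#'
#' Pairs each subject's trait total with AUROC2, removes bivariate
#' Mahalanobis outliers, and reports Pearson and Spearman tests (the dual
#' reporting used in this literature).
#'
#' @param trait numeric per-subject trait totals.
#' @param auroc2 numeric per-subject AUROC2.
#' @param alpha_cut Mahalanobis tail cut, see [mahalanobis_exclude()].
#' @return list with `pearson`, `spearman`, `n_excluded`, `excluded`.
#' @export
metacog_trait_correlation <- function(trait, auroc2, alpha_cut = 0.001) {
  keep <- is.finite(trait) & is.finite(auroc2)
  scr <- mahalanobis_exclude(trait, auroc2, alpha_cut)
  use <- scr$retained
  list(pearson = correlation_test(trait[use], auroc2[use], "pearson"),
       spearman = correlation_test(trait[use], auroc2[use], "spearman"),
       n_excluded = length(scr$excluded) + sum(!keep),
       excluded = scr$excluded)
}
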