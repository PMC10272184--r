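## Questionnaire scoring: social anxiety (LSAS) and autistic traits (AQ),
## chained-equation imputation, reliability, and distribution summaries.

#' Default AQ item-direction key
#'
#' The 50-item Autism-Spectrum Quotient is scored dichotomously: one point per
#' item answered in the autistic-trait direction ("definitely"/"slightly"
#' collapsed). This returns the standard published key as a logical vector,
#' `TRUE` for items where *agreement* indicates autistic traits.
#'
#' @return logical vector of length 50.
#' @export
aq_default_key <- function() {
  agree <- c(2, 4, 5, 6, 7, 9, 12, 13, 16, 18, 19, 20, 21, 22, 23, 26,
             33, 35, 39, 41, 42, 43, 45, 46)
  seq_len(50) %in% agree
}

#' Score the Liebowitz Social Anxiety Scale
#'
#' The LSAS presents 24 social situations, each rated for fear (0-3) and for
#' avoidance (0-3); the total is the sum of all 48 ratings (range 0-144),
#' higher meaning more severe social anxiety.
#'
#' @param items numeric vector of 48 ratings in `{0,1,2,3}` for one subject,
#'   or a matrix / data.frame with one row per subject and 48 columns.
#'   Missing values are allowed (impute first with [impute_items()] if a
#'   complete total is required).
#' @return numeric total (or vector of totals), `NA` if any item is missing.
#' @export
score_lsas <- function(items) {
  m <- as.matrix(items)
  if (is.vector(items) && is.null(dim(items))) m <- matrix(as.numeric(items), nrow = 1L)
  if (ncol(m) != 48L)
    stop_mimicog("LSAS requires 48 item responses (24 fear + 24 avoidance)", "mimicog_validation_error")
  vals <- m[!is.na(m)]
  if (length(vals) && (any(vals < 0 | vals > 3) || any(vals != round(vals))))
    stop_mimicog("LSAS items must be integers in 0..3", "mimicog_validation_error")
  tot <- rowSums(m)
  if (length(tot) == 1L) unname(tot) else tot
}

#' Score the Autism-Spectrum Quotient
#'
#' Responses use a 4-point scale, 1 = definitely agree ... 4 = definitely
#' disagree. Each item scores one point when answered in the keyed
#' (autistic-trait) direction, collapsing "definitely" and "slightly":
#' responses 1-2 for agree-keyed items, responses 3-4 for disagree-keyed
#' items. Totals range 0-50; the conventional clinical-significance cut-off
#' is a total strictly greater than 32.
#'
#' @param items numeric vector of 50 responses in `{1,2,3,4}` (or matrix /
#'   data.frame, one row per subject).
#' @param key logical vector of length 50, `TRUE` where agreement is keyed as
#'   autistic-trait direction; defaults to [aq_default_key()].
#' @return numeric total (or vector of totals), `NA` if any item is missing.
#' @export
score_aq <- function(items, key = aq_default_key()) {
  if (is.null(key)) stop_mimicog("an AQ item-direction key is required", "mimicog_config_error")
  key <- as.logical(key)
  if (length(key) != 50L || anyNA(key))
    stop_mimicog("AQ key must be a logical vector of length 50", "mimicog_config_error")
  m <- as.matrix(items)
  if (is.vector(items) && is.null(dim(items))) m <- matrix(as.numeric(items), nrow = 1L)
  if (ncol(m) != 50L)
    stop_mimicog("AQ requires 50 item responses", "mimicog_validation_error")
  vals <- m[!is.na(m)]
  if (length(vals) && (any(vals < 1 | vals > 4) || any(vals != round(vals))))
    stop_mimicog("AQ items must be integers in 1..4", "mimicog_validation_error")
  pts <- ifelse(rep(key, each = nrow(m)), m <= 2, m >= 3)
  tot <- rowSums(matrix(pts, nrow = nrow(m)))
  if (length(tot) == 1L) unname(tot) else tot
}

#' Impute missing questionnaire items by chained equations
#'
#' Missing entries are filled by predictive-mean-matching-style chained
#' equations: each incomplete item is regressed on all other items over
#' complete rows, predictions for the missing rows are matched to the nearest
#' observed donors, and one donor value is drawn. This is repeated for
#' `n_imputations` independent draws whose average is rounded back to the item
#' scale, yielding a single deterministic completed table.
#'
#' Subjects with an entirely missing questionnaire cannot be imputed and are
#' flagged for exclusion (attribute `"excluded_subjects"`, rows left `NA`).
#'
#' @param item_table matrix or data.frame, one row per subject, one column per
#'   item, on a common integer scale.
#' @param n_imputations number of chained-equation draws to average (5 by
#'   default).
#' @param seed integer seed; the completed table is reproducible under it.
#' @param range optional `c(min, max)` of the item scale; inferred from the
#'   observed values when omitted.
#' @param n_sweeps chained-equation sweeps per draw.
#' @return the completed table (same class as the input) with attribute
#'   `excluded_subjects` listing row indices that were fully missing.
#' @export
impute_items <- function(item_table, n_imputations = 5L, seed = 1L,
                         range = NULL, n_sweeps = 5L) {
  m <- as.matrix(item_table)
  storage.mode(m) <- "double"
  if (!anyNA(m)) {
    attr(item_table, "excluded_subjects") <- integer(0)
    return(item_table)
  }
  all_missing <- which(rowSums(!is.na(m)) == 0L)
  partial <- setdiff(seq_len(nrow(m)), all_missing)
  frac_missing <- rowMeans(is.na(m[partial, , drop = FALSE]))
  if (any(frac_missing >= 0.10))
    stop_mimicog("per-subject missingness must be below 10% (fully missing subjects are flagged instead)",
                 "mimicog_validation_error")
  if (is.null(range)) range <- base::range(m, na.rm = TRUE)

  miss_idx <- which(is.na(m), arr.ind = TRUE)
  miss_idx <- miss_idx[miss_idx[, 1L] %in% partial, , drop = FALSE]
  draws <- matrix(NA_real_, nrow = nrow(miss_idx), ncol = n_imputations)

  for (d in seq_len(n_imputations)) {
    set.seed(child_seed(seed, paste0("impute", d)))
    mm <- m
    ## initialise holes with random observed values of the same item
    for (k in seq_len(nrow(miss_idx))) {
      j <- miss_idx[k, 2L]
      obs <- m[!is.na(m[, j]), j]
      mm[miss_idx[k, 1L], j] <- if (length(obs)) sample(obs, 1L) else mean(range)
    }
    items_with_na <- unique(miss_idx[, 2L])
    for (sweep in seq_len(n_sweeps)) {
      for (j in items_with_na) {
        rows_na <- miss_idx[miss_idx[, 2L] == j, 1L]
        obs_rows <- setdiff(which(!is.na(m[, j])), rows_na)
        X <- cbind(1, mm[, -j, drop = FALSE])
        fit <- lm.fit(X[obs_rows, , drop = FALSE], m[obs_rows, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred_obs <- drop(X[obs_rows, , drop = FALSE] %*% beta)
        pred_na <- drop(X[rows_na, , drop = FALSE] %*% beta)
        for (ii in seq_along(rows_na)) {
          dist <- abs(pred_obs - pred_na[ii])
          donors <- obs_rows[order(dist)][seq_len(min(3L, length(obs_rows)))]
          mm[rows_na[ii], j] <- m[sample(rep(donors, 2L), 1L), j]
        }
      }
    }
    draws[, d] <- mm[miss_idx]
  }
  filled <- pmin(range[2L], pmax(range[1L], round(rowMeans(draws))))
  out <- m
  out[miss_idx] <- filled
  res <- item_table
  if (is.data.frame(item_table)) {
    res[] <- as.data.frame(out)
  } else {
    res <- out
  }
  attr(res, "excluded_subjects") <- all_missing
  res
}

#' Cronbach's alpha with a subject bootstrap confidence interval
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the total)`.
#'
#' @param item_table matrix/data.frame, subjects x items, no missing values.
#' @param n_boot bootstrap resamples of subjects for the percentile CI
#'   (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return an object of class `mimicog_reliability`: list with `alpha`,
#'   `ci_low`, `ci_high`, `k`, `n`.
#' @export
cronbach_alpha <- function(item_table, n_boot = 1000L, seed = 1L, conf = 0.95) {
  m <- as.matrix(item_table)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L || nrow(m) < 3L)
    stop_mimicog("alpha needs at least 2 items and 3 subjects", "mimicog_validation_error")
  if (anyNA(m))
    stop_mimicog("alpha requires complete data; impute first", "mimicog_validation_error")
  alpha_of <- function(x) {
    tv <- var(rowSums(x))
    if (tv == 0) return(NA_real_)
    k <- ncol(x)
    k / (k - 1) * (1 - sum(apply(x, 2L, var)) / tv)
  }
  a <- alpha_of(m)
  if (is.na(a))
    stop_mimicog("total-score variance is zero; alpha undefined", "mimicog_degenerate_error")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(child_seed(seed, "alpha_boot"))
    ab <- replicate(n_boot, alpha_of(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]))
    ci <- quantile(ab, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE, names = FALSE)
  }
  structure(list(alpha = a, ci_low = ci[1L], ci_high = ci[2L],
                 k = ncol(m), n = nrow(m), conf = conf),
            class = "mimicog_reliability")
}

#' @export
print.mimicog_reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f, %d%% CI [%.3f, %.3f] (k = %d items, n = %d)\n",
              x$alpha, round(100 * x$conf), x$ci_low, x$ci_high, x$k, x$n))
  invisible(x)
}

#' Distribution summary of a trait score
#'
#' Mean, SD, Pearson skewness, non-excess kurtosis (normal = 3), and
#' strict-inequality cut-off tallies with percentages rounded to two
#' decimals.
#'
#' @param x numeric vector of totals (length >= 2); `NA` dropped.
#' @param cutoff optional scalar; subjects with `x > cutoff` are counted.
#' @return list with `n, mean, sd, min, max, skewness, kurtosis` and, when a
#'   cutoff is given, `n_above, pct_above`.
#' @export
trait_summary <- function(x, cutoff = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop_mimicog("trait_summary needs at least 2 subjects", "mimicog_validation_error")
  out <- list(n = length(x), mean = mean(x), sd = sd(x),
              min = min(x), max = max(x),
              skewness = moment_skewness(x), kurtosis = moment_kurtosis(x))
  if (!is.null(cutoff)) {
    out$cutoff <- cutoff
    out$n_above <- sum(x > cutoff)
    out$pct_above <- round(100 * out$n_above / out$n, 2L)
  }
  out
}

#' Score a full trait table from item responses
#'
#' Applies imputation (if needed) and scoring to LSAS and AQ item tables and
#' returns one row per subject with totals and cut-off flags (LSAS > 30,
#' AQ > 32).
#'
#' @param lsas_items subjects x 48 table of LSAS ratings (0-3).
#' @param aq_items subjects x 50 table of AQ responses (1-4).
#' @param key AQ item-direction key, see [score_aq()].
#' @param impute impute missing items first (default TRUE).
#' @param seed seed for the imputation draws.
#' @return data.frame with `subject_id`, `lsas_total`, `aq_total`,
#'   `lsas_above_cutoff`, `aq_above_cutoff`; subjects whose AQ (or LSAS) was
#'   entirely missing keep `NA` totals.
#' @export
score_questionnaires <- function(lsas_items, aq_items, key = aq_default_key(),
                                 impute = TRUE, seed = 1L) {
  if (impute) {
    lsas_items <- impute_items(lsas_items, seed = child_seed(seed, "lsas"), range = c(0, 3))
    aq_items <- impute_items(aq_items, seed = child_seed(seed, "aq"), range = c(1, 4))
  }
  lt <- score_lsas(lsas_items)
  at <- score_aq(aq_items, key)
  data.frame(subject_id = seq_along(lt),
             lsas_total = lt, aq_total = at,
             lsas_above_cutoff = lt > 30, aq_above_cutoff = at > 32)
}
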