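## Emotion-recognition scoring from six-category slider ratings.

slider_cols <- function() paste0("slider_", EMOTION_CATEGORIES)

slider_matrix <- function(ratings) {
  cols <- slider_cols()
  missing_cols <- setdiff(cols, names(ratings))
  if (length(missing_cols))
    stop_mimicog(paste("missing slider columns:", paste(missing_cols, collapse = ", ")),
                 "mimicog_validation_error")
  m <- as.matrix(ratings[cols])
  colnames(m) <- EMOTION_CATEGORIES
  m
}

#' Score emotion-recognition accuracy from slider ratings
#'
#' The responded category is the one with the highest slider score. A trial
#' is correct (1) when the unique maximum falls on the true category,
#' incorrect (0) when it falls elsewhere, and discounted (`NA`) when the
#' maximum is tied between two or more categories (the response is then
#' ambiguous).
#'
#' @param ratings data.frame with `true_category` and the six
#'   `slider_<category>` columns on the 11-point grid.
#' @return numeric vector: 1, 0 or `NA` (discounted) per trial.
#' @export
score_accuracy <- function(ratings) {
  m <- slider_matrix(ratings)
  if (!all(is_on_grid(m)))
    stop_mimicog("slider values must lie on the grid 0, 10, ..., 100",
                 "mimicog_validation_error")
  if (!all(ratings$true_category %in% EMOTION_CATEGORIES))
    stop_mimicog("unknown true_category label", "mimicog_validation_error")
  mx <- apply(m, 1L, max)
  n_at_max <- rowSums(m == mx)
  winner <- EMOTION_CATEGORIES[max.col(m, ties.method = "first")]
  out <- as.numeric(winner == ratings$true_category)
  out[n_at_max > 1L] <- NA_real_
  out
}

#' Relative accuracy score
#'
#' Slider score of the true category minus the mean slider score of the five
#' other categories (range -100..100); defined regardless of ties.
#'
#' @inheritParams score_accuracy
#' @return numeric vector of relative accuracy scores.
#' @export
relative_accuracy <- function(ratings) {
  m <- slider_matrix(ratings)
  idx <- match(ratings$true_category, EMOTION_CATEGORIES)
  true_val <- m[cbind(seq_len(nrow(m)), idx)]
  true_val - (rowSums(m) - true_val) / 5
}

#' Score a full ratings table
#'
#' @inheritParams score_accuracy
#' @return the input with `correct` (1/0/`NA`), `discounted` (logical) and
#'   `relative_accuracy` columns appended.
#' @export
score_ratings <- function(ratings) {
  ratings$correct <- score_accuracy(ratings)
  ratings$discounted <- is.na(ratings$correct)
  ratings$relative_accuracy <- relative_accuracy(ratings)
  ratings
}
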