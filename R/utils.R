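## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One global seed fans out to per-stage child seeds so that each stage is
#' individually reproducible. The derived seed always fits in a 32-bit
#' integer.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

## Standardize to mean 0 / SD 1; degenerate input maps to zeros so that a
## two-subject fixture does not produce NaN trait covariates.
z_std <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

## Round to the nearest slider grid point and clip into [0, 100].
snap_to_grid <- function(x) {
  pmin(100L, pmax(0L, as.integer(round(x / 10) * 10)))
}

is_on_grid <- function(x) {
  !is.na(x) & x %in% SLIDER_GRID
}

## Moments used by trait_summary(): Pearson skewness and NON-excess kurtosis
## (normal = 3), computed with the biased (1/n) central moments.
moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2
}

## Fast integer group id for a few parallel vectors (numeric-sortable, used
## with rowsum() on multi-million-row epoch frames where interaction() is too
## slow).
group_id <- function(...) {
  vecs <- list(...)
  id <- numeric(length(vecs[[1L]]))
  for (v in vecs) {
    u <- sort(unique(v))
    id <- id * length(u) + (match(v, u) - 1L)
  }
  id
}

## Missing-aware group means keyed by a numeric group id; returns values
## aligned to sort(unique(g)). Groups with no non-missing value give NA.
group_mean <- function(v, g) {
  ok <- !is.na(v)
  sums <- rowsum(ifelse(ok, v, 0), g)
  cnts <- rowsum(as.numeric(ok), g)
  out <- drop(sums / cnts)
  out[cnts == 0] <- NA_real_
  out
}

stop_mimicog <- function(msg, class) {
  stop(structure(class = c(class, "mimicog_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
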