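## Trait-moderation statistics: (generalized) linear mixed models with
## crossed random intercepts, sum-coded category contrasts, bootstrapped
## category-averaged EMG models, and per-emotion EMG -> accuracy models.

#' Fit a mixed model with crossed random intercepts
#'
#' Binomial outcomes use `lme4::glmer` (Laplace approximation; `nAGQ = 0`
#' selects lme4's fast penalized update, which large simulation loops use),
#' Gaussian outcomes `lme4::lmer` (REML). Per-term omnibus tests are
#' type-II likelihood-ratio chi-squares for binomial models and F tests (from
#' the sequential ANOVA decomposition with residual denominator df) for
#' Gaussian models. Non-convergence is flagged in the result, never silent.
#'
#' @param formula model formula including `(1|...)` random-intercept terms.
#' @param data tidy long data; rows with missing outcome are dropped.
#' @param family `"binomial"` or `"gaussian"`.
#' @param nAGQ integration setting for binomial fits (1 = Laplace).
#' @param omnibus compute per-term omnibus tests (costs extra refits for
#'   binomial models).
#' @return object of class `mimicog_fit`: list with `coefficients`
#'   (data.frame: term, estimate, se, statistic, df, p, odds_ratio),
#'   `omnibus`, `model`, `family`, `converged`, `messages`.
#' @export
fit_mixed <- function(formula, data, family = c("binomial", "gaussian"),
                      nAGQ = 1, omnibus = TRUE) {
  family <- match.arg(family)
  msgs <- character()
  fit <- tryCatch(
    withCallingHandlers(
      if (family == "binomial")
        lme4::glmer(formula, data = data, family = stats::binomial(), nAGQ = nAGQ,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      else
        lme4::lmer(formula, data = data, REML = TRUE),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    ## hard failure (e.g. complete separation): flagged, never silent
    return(structure(list(
      coefficients = data.frame(term = character(), estimate = numeric(),
                                se = numeric(), statistic = numeric(),
                                df = numeric(), p = numeric(),
                                odds_ratio = numeric()),
      omnibus = NULL, model = NULL, family = family, converged = FALSE,
      messages = c(msgs, conditionMessage(fit))), class = "mimicog_fit"))
  }
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("converge", msgs, ignore.case = TRUE))

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      statistic = sm[, 3L], row.names = NULL)
  if (family == "binomial") {
    coefs$df <- NA_real_
    coefs$p <- 2 * pnorm(-abs(coefs$statistic))
    coefs$odds_ratio <- exp(coefs$estimate)
  } else {
    rdf <- stats::nobs(fit) - nrow(sm)
    coefs$df <- rdf
    coefs$p <- 2 * pt(-abs(coefs$statistic), rdf)
    coefs$odds_ratio <- NA_real_
  }

  omni <- NULL
  if (omnibus) {
    omni <- tryCatch(.omnibus_tests(fit, formula, data, family, nAGQ),
                     error = function(e) {
                       msgs <<- c(msgs, conditionMessage(e)); NULL
                     })
  }
  structure(list(coefficients = coefs, omnibus = omni, model = fit,
                 family = family, converged = converged, messages = msgs),
            class = "mimicog_fit")
}

## Type-II omnibus tests: each term is tested against the largest model that
## respects marginality (interactions tested against the full model, main
## effects against the no-interaction model).
.omnibus_tests <- function(fit, formula, data, family, nAGQ) {
  if (family == "gaussian") {
    av <- anova(fit)   # sequential F decomposition
    rdf <- stats::nobs(fit) - length(lme4::fixef(fit))
    return(data.frame(term = rownames(av), statistic = av$`F value`,
                      df = av$npar, den_df = rdf,
                      p = pf(av$`F value`, av$npar, rdf, lower.tail = FALSE),
                      test = "F", row.names = NULL))
  }
  full_ml <- fit   # glmer fits are already ML
  tl <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  out <- lapply(tl, function(tm) {
    is_inter <- grepl(":", tm, fixed = TRUE)
    base_terms <- if (is_inter) tl else tl[!grepl(":", tl, fixed = TRUE)]
    f_base <- stats::reformulate(c(base_terms, .rebars(formula)),
                                 response = as.character(formula[[2L]]))
    f_red <- stats::reformulate(c(setdiff(base_terms, tm), .rebars(formula)),
                                response = as.character(formula[[2L]]))
    m1 <- if (identical(sort(base_terms), sort(tl))) full_ml else
      lme4::glmer(f_base, data = data, family = stats::binomial(), nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    m0 <- lme4::glmer(f_red, data = data, family = stats::binomial(), nAGQ = nAGQ,
                      control = lme4::glmerControl(calc.derivs = FALSE))
    chi <- as.numeric(2 * (logLik(m1) - logLik(m0)))
    dfd <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
    data.frame(term = tm, statistic = chi, df = dfd, den_df = NA_real_,
               p = pchisq(chi, dfd, lower.tail = FALSE), test = "LRT")
  })
  do.call(rbind, out)
}

.rebars <- function(formula) {
  vapply(lme4::findbars(formula),
         function(b) paste0("(", deparse(b), ")"), character(1L))
}

#' @export
print.mimicog_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s mixed model%s\n", x$family,
              if (x$converged) "" else " [DID NOT CONVERGE]"))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.null(x$omnibus)) {
    cat("\nOmnibus tests:\n")
    print(format(x$omnibus, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Reconstruct the omitted sum-coded category deviation
#'
#' With sum coding over k categories, only k-1 deviations are estimated; the
#' omitted category's deviation is minus their sum. Its standard error comes
#' from the contrast variance `c' V c` over the fixed-effect covariance, and
#' it is tested with a z-test (general hypothesis test). Applied to the main
#' category effect and, when present, to each category-by-covariate
#' interaction block.
#'
#' @param fit a `mimicog_fit` whose model used `contr.sum` on `factor_name`.
#' @param factor_name name of the sum-coded factor in the model.
#' @param levels_order the factor's levels in the order used for coding (the
#'   last one is the omitted level); taken from the fitted model frame when
#'   omitted.
#' @return data.frame of per-level deviations (estimate, se, z, p) including
#'   the reconstructed omitted level, one block per term group.
#' @export
sum_coding_contrasts <- function(fit, factor_name = "category",
                                 levels_order = NULL) {
  if (is.null(levels_order))
    levels_order <- levels(stats::model.frame(fit$model)[[factor_name]])
  V <- as.matrix(vcov(fit$model))
  est <- lme4::fixef(fit$model)
  k <- length(levels_order)
  pat <- paste0("^", factor_name, "[0-9]+$")
  groups <- list(main = grep(pat, names(est), value = TRUE))
  inter <- grep(paste0(factor_name, "[0-9]+:|:", factor_name, "[0-9]+"),
                names(est), value = TRUE)
  if (length(inter)) {
    partner <- gsub(paste0(factor_name, "[0-9]+:?|:?", factor_name, "[0-9]+"), "", inter)
    for (p in unique(partner)) groups[[paste0("interaction:", p)]] <- inter[partner == p]
  }
  out <- list()
  for (g in names(groups)) {
    nm <- groups[[g]]
    if (length(nm) != k - 1L) next
    if (is.null(V) || !all(nm %in% rownames(V)))
      stop_mimicog("fixed-effect covariance unavailable", "mimicog_internal_error")
    e <- est[nm]
    se <- sqrt(diag(V[nm, nm, drop = FALSE]))
    cc <- rep(-1, k - 1L)
    e_k <- sum(cc * e)
    se_k <- sqrt(drop(t(cc) %*% V[nm, nm] %*% cc))
    d <- data.frame(block = g, level = levels_order,
                    estimate = c(e, e_k), se = c(se, se_k))
    d$z <- d$estimate / d$se
    d$p <- 2 * pnorm(-abs(d$z))
    out[[g]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear models on category-averaged EMG with a cluster bootstrap
#'
#' OLS of category-averaged muscle activity on emotion category (treatment
#' coding, neutral reference), a standardized trait score and their
#' interaction. Because residuals of these models are typically non-normal,
#' non-parametric percentile confidence intervals are computed by resampling
#' subjects (with all their category rows) `n_boot` times.
#'
#' @param cat_avg category-averaged EMG (`subject_id`, `category`, `value`)
#'   for one muscle.
#' @param trait_z per-subject standardized trait values, aligned to
#'   `sort(unique(cat_avg$subject_id))`.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for reproducible resampling.
#' @param conf confidence level.
#' @return list with `coefficients` (estimate, boot se, percentile CI),
#'   `model` (the lm fit), `n_boot`.
#' @export
fit_lm_category_emg <- function(cat_avg, trait_z, n_boot = 1000L, seed = 1L,
                                conf = 0.95) {
  subs <- sort(unique(cat_avg$subject_id))
  if (length(subs) < 20L)
    warning("fewer than 20 subjects; bootstrap intervals may be unstable")
  d <- cat_avg[!is.na(cat_avg$value), ]
  d$category <- stats::relevel(factor(d$category, levels = EMOTION_CATEGORIES),
                               ref = "neutral")
  d$trait_z <- trait_z[match(d$subject_id, subs)]
  m <- lm(value ~ category * trait_z, data = d)
  bcoef <- matrix(NA_real_, n_boot, length(coef(m)),
                  dimnames = list(NULL, names(coef(m))))
  set.seed(child_seed(seed, "cluster_boot"))
  for (b in seq_len(n_boot)) {
    pick <- sample(subs, replace = TRUE)
    db <- do.call(rbind, lapply(seq_along(pick), function(i) {
      rows <- d[d$subject_id == pick[i], ]
      rows$subject_id <- i   # relabel so duplicates stay distinct clusters
      rows
    }))
    cf <- tryCatch(coef(lm(value ~ category * trait_z, data = db)),
                   error = function(e) NULL)
    if (!is.null(cf)) bcoef[b, names(cf)] <- cf
  }
  a <- (1 - conf) / 2
  ci <- t(apply(bcoef, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  coefs <- data.frame(term = names(coef(m)), estimate = unname(coef(m)),
                      boot_se = apply(bcoef, 2L, sd, na.rm = TRUE),
                      ci_low = ci[, 1L], ci_high = ci[, 2L], row.names = NULL)
  list(coefficients = coefs, model = m, n_boot = n_boot, conf = conf)
}

#' Per-emotion mimicry -> recognition-accuracy mixed models
#'
#' Restricts the data to one emotion's recognition trials and fits a binomial
#' mixed model of accuracy on the trial-averaged EMG z-scores of the listed
#' muscles, the standardized trait, and trait-by-muscle interactions, with
#' crossed random intercepts for subject and stimulus. Models of happiness
#' conventionally include both muscles; anger/sadness/fear use the corrugator
#' only.
#'
#' @param scored scored ratings (needs `subject_id`, `stimulus_id`,
#'   `true_category`, `correct`).
#' @param trial_avg trial-averaged EMG (`subject_id`, `muscle`,
#'   `stimulus_id`, `value`).
#' @param emotion one of the six category labels.
#' @param trait_z per-subject standardized trait, aligned to
#'   `sort(unique(scored$subject_id))`.
#' @param muscles predictors to include; default picks both muscles for
#'   happiness, corrugator otherwise.
#' @param nAGQ,omnibus passed to [fit_mixed()].
#' @return a `mimicog_fit`; quasi-separation (fitted probabilities at the
#'   0/1 boundary) is reported in `messages`.
#' @export
fit_emg_accuracy <- function(scored, trial_avg, emotion, trait_z,
                             muscles = NULL, nAGQ = 1, omnibus = FALSE) {
  stopifnot(emotion %in% EMOTION_CATEGORIES)
  if (is.null(muscles))
    muscles <- if (emotion == "happiness") c("corrugator", "zygomaticus")
               else "corrugator"
  subs <- sort(unique(scored$subject_id))
  d <- scored[scored$true_category == emotion & !is.na(scored$correct), ]
  for (m in muscles) {
    e <- trial_avg[trial_avg$muscle == m, ]
    d[[m]] <- e$value[match(paste(d$subject_id, d$stimulus_id),
                            paste(e$subject_id, e$stimulus_id))]
  }
  d$trait_z <- trait_z[match(d$subject_id, subs)]
  d <- d[complete.cases(d[c("correct", "trait_z", muscles)]), ]
  rhs <- paste(paste0("trait_z * ", muscles, collapse = " + "),
               "+ (1 | subject_id) + (1 | stimulus_id)")
  fit <- fit_mixed(as.formula(paste("correct ~", rhs)), d,
                   family = "binomial", nAGQ = nAGQ, omnibus = omnibus)
  if (is.null(fit$model)) return(fit)
  p_hat <- stats::fitted(fit$model)
  if (mean(p_hat > 1 - 1e-6 | p_hat < 1e-6) > 0.05)
    fit$messages <- c(fit$messages,
                      "possible quasi-separation: fitted probabilities at the boundary")
  fit
}

#' Trait-by-category mixed model on accuracy or confidence
#'
#' The headline moderation models: binomial mixed model on accuracy or
#' Gaussian mixed model on confidence with sum-coded emotion category, one
#' standardized trait, and their interaction as fixed effects, plus crossed
#' random intercepts for subject and stimulus.
#'
#' @param scored scored ratings table (from [score_ratings()]).
#' @param trait_z per-subject standardized trait, aligned to
#'   `sort(unique(scored$subject_id))`.
#' @param outcome `"accuracy"` (binomial, discounted trials dropped) or
#'   `"confidence"` (gaussian).
#' @param nAGQ,omnibus passed to [fit_mixed()].
#' @return a `mimicog_fit`.
#' @export
fit_trait_category_model <- function(scored, trait_z,
                                     outcome = c("accuracy", "confidence"),
                                     nAGQ = 1, omnibus = FALSE) {
  outcome <- match.arg(outcome)
  subs <- sort(unique(scored$subject_id))
  d <- scored
  d$trait_z <- trait_z[match(d$subject_id, subs)]
  ## neutral last: contr.sum omits the final level, whose deviation is then
  ## reconstructed by general hypothesis testing (sum_coding_contrasts)
  lev <- c(setdiff(EMOTION_CATEGORIES, "neutral"), "neutral")
  d$category <- factor(d$true_category, levels = lev)
  stats::contrasts(d$category) <- stats::contr.sum(length(lev))
  if (outcome == "accuracy") {
    d <- d[!is.na(d$correct), ]
    fit_mixed(correct ~ category * trait_z + (1 | subject_id) + (1 | stimulus_id),
              d, family = "binomial", nAGQ = nAGQ, omnibus = omnibus)
  } else {
    fit_mixed(confidence ~ category * trait_z + (1 | subject_id) + (1 | stimulus_id),
              d, family = "gaussian", omnibus = omnibus)
  }
}
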