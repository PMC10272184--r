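## End-to-end orchestration: config handling, input validation, stage
## execution, stage outputs and a summary report.

#' Pipeline configuration with full defaulting
#'
#' Defaults reproduce the reference analysis settings: 3.5 SD artifact
#' criterion with the strict >50% exclusion rules, 28-500 Hz band-pass with a
#' 50 Hz notch (order 4), 1000 bootstrap iterations for the category-averaged
#' EMG models, and a chi-square(2) Mahalanobis cut at 0.001.
#'
#' @param seed master seed (fans out to stage seeds).
#' @param n_subjects simulated sample size.
#' @param effects a [sim_effects()] object (or a named list of overrides).
#' @param filter list with `band`, `notch`, `order`.
#' @param z_threshold artifact SD criterion.
#' @param mahalanobis_alpha tail cut for bivariate outlier screening.
#' @param n_boot bootstrap iterations for EMG linear models.
#' @param emg_mode `"epochs"` (fast bin-level synthesis), `"raw"` (1000 Hz
#'   signal) or `"none"`.
#' @param nAGQ integration setting for binomial mixed fits.
#' @param out_dir output directory for stage files and the report.
#' @param ratings_file,emg_file optional externally supplied data (real-data
#'   mode); when given, the simulate stage is skipped.
#' @param traits_file optional external trait totals CSV.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 57L,
                            effects = sim_effects(),
                            filter = list(band = c(28, 500), notch = 50, order = 4),
                            z_threshold = 3.5, mahalanobis_alpha = 0.001,
                            n_boot = 1000L, emg_mode = c("epochs", "raw", "none"),
                            nAGQ = 1, out_dir = "mimicog_out",
                            ratings_file = NULL, emg_file = NULL,
                            traits_file = NULL) {
  if (!inherits(effects, "sim_effects"))
    effects <- do.call(sim_effects, as.list(effects))
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 effects = effects, filter = filter, z_threshold = z_threshold,
                 mahalanobis_alpha = mahalanobis_alpha,
                 n_boot = as.integer(n_boot), emg_mode = match.arg(emg_mode),
                 nAGQ = nAGQ, out_dir = out_dir,
                 ratings_file = ratings_file, emg_file = emg_file,
                 traits_file = traits_file),
            class = "pipeline_config")
}

#' Read a JSON config file, merging over the defaults
#'
#' @param path JSON file; any subset of the [pipeline_config()] fields.
#' @param ... overrides applied on top of the file (e.g. from CLI flags).
#' @export
read_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$effects)) raw$effects <- do.call(sim_effects, raw$effects)
  raw <- modifyList(raw, list(...))
  do.call(pipeline_config, raw)
}

#' Validate input files against the pipeline schemas
#'
#' Checks that sliders and confidence lie on the 11-point grid, category
#' labels are known, both muscle channels are present, the sampling rate is
#' 1000 Hz and marker onsets are strictly increasing per subject. Row and
#' column counts are collected alongside an itemized violation list.
#'
#' @param paths named list with any of `ratings` (CSV), `emg_raw` (CSV),
#'   `emg_meta` (JSON with `fs` and `markers`), `traits` (CSV).
#' @return object of class `validation_report`: list with `violations`
#'   (character) and `counts`.
#' @export
validate_inputs <- function(paths) {
  v <- character(); counts <- list()
  if (!is.null(paths$ratings)) {
    r <- read.csv(paths$ratings)
    counts$ratings <- dim(r)
    need <- c("subject_id", "stimulus_id", "true_category", slider_cols(), "confidence")
    miss <- setdiff(need, names(r))
    if (length(miss)) v <- c(v, paste("ratings: missing columns:", paste(miss, collapse = ", ")))
    if (!length(miss)) {
      for (cc in c(slider_cols(), "confidence")) {
        bad <- !is_on_grid(r[[cc]])
        if (any(bad)) v <- c(v, sprintf("ratings: %d off-grid value(s) in %s (e.g. %s)",
                                        sum(bad), cc, r[[cc]][which(bad)[1L]]))
      }
      badc <- !r$true_category %in% EMOTION_CATEGORIES
      if (any(badc)) v <- c(v, sprintf("ratings: %d unknown category label(s)", sum(badc)))
    }
  }
  if (!is.null(paths$emg_raw)) {
    e <- read.csv(paths$emg_raw)
    counts$emg_raw <- dim(e)
    miss <- setdiff(c("subject_id", "muscle", "t_ms", "value"), names(e))
    if (length(miss)) v <- c(v, paste("emg: missing columns:", paste(miss, collapse = ", ")))
    if (!length(miss)) {
      got <- unique(e$muscle)
      for (m in c("corrugator", "zygomaticus"))
        if (!m %in% got) v <- c(v, paste("emg: missing muscle channel:", m))
    }
  }
  if (!is.null(paths$emg_meta)) {
    meta <- jsonlite::read_json(paths$emg_meta, simplifyVector = TRUE)
    if (!identical(as.numeric(meta$fs), 1000)) v <- c(v, "emg meta: fs must be 1000 Hz")
    mk <- meta$markers
    if (!is.null(mk)) {
      counts$markers <- dim(mk)
      nonmono <- vapply(split(mk$onset_ms, mk$subject_id),
                        function(o) any(diff(o) <= 0), logical(1L))
      if (any(nonmono)) v <- c(v, "emg meta: marker onsets not strictly increasing")
    }
  }
  if (!is.null(paths$traits)) {
    tr <- read.csv(paths$traits)
    counts$traits <- dim(tr)
    miss <- setdiff(c("subject_id", "lsas_total", "aq_total"), names(tr))
    if (length(miss)) v <- c(v, paste("traits: missing columns:", paste(miss, collapse = ", ")))
  }
  structure(list(violations = v, counts = counts), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!length(x$violations)) cat("All inputs valid.\n")
  else cat("Violations:\n", paste(" -", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

.log <- function(...) message("[mimicog] ", ...)

#' Run the full pipeline
#'
#' Executes simulate -> questionnaires -> EMG preprocessing -> behaviour ->
#' metacognition -> models, writing each stage's outputs as CSV/JSON under
#' `config$out_dir` plus a `report.md` summarizing per-category accuracy and
#' confidence, AUROC2-trait correlations and model coefficients. When
#' `config$ratings_file` is set, the simulate stage is skipped and external
#' data are used.
#'
#' @param config a [pipeline_config()].
#' @param keep_going continue past stage errors (failed stages are reported
#'   in the returned `status`).
#' @return (invisibly) list of stage results plus `status`, a named character
#'   vector `"ok"`/`"failed: <message>"` per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_going = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(); status <- character()
  run_stage <- function(name, expr) {
    .log("stage: ", name)
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(out))
      .log("stage ", name, " FAILED: ", conditionMessage(out))
      if (!keep_going) stop("pipeline halted at stage '", name, "': ",
                            conditionMessage(out), call. = FALSE)
      return(NULL)
    }
    status[[name]] <- "ok"; status <<- status
    out
  }
  op <- function(f) file.path(config$out_dir, f)

  external <- !is.null(config$ratings_file)
  if (!external) {
    sim <- run_stage("simulate", simulate_study(
      config$n_subjects, config$effects, config$seed, emg = config$emg_mode))
    if (is.null(sim)) return(invisible(list(status = status)))
    res$traits <- sim$traits
    res$design <- sim$design
    ratings <- sim$ratings$ratings
    emg <- sim$emg
    write.csv(sim$design$stimuli, op("design.csv"), row.names = FALSE)
    write.csv(res$traits, op("traits.csv"), row.names = FALSE)
    write.csv(ratings, op("ratings.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(effects = unclass(sim$ground_truth$effects),
           seed = config$seed),
      op("ground_truth.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  } else {
    ratings <- run_stage("load", read.csv(config$ratings_file))
    res$traits <- if (!is.null(config$traits_file)) read.csv(config$traits_file) else NULL
    emg <- NULL
    res$design <- NULL
  }

  qn <- run_stage("questionnaires", {
    tr <- res$traits
    data.frame(subject_id = tr$subject_id,
               lsas_total = tr$lsas_total, aq_total = tr$aq_total,
               lsas_z = z_std(tr$lsas_total), aq_z = z_std(tr$aq_total),
               lsas_above_cutoff = tr$lsas_total > 30,
               aq_above_cutoff = tr$aq_total > 32)
  })

  scored <- run_stage("behaviour", score_ratings(ratings))
  if (!is.null(scored)) {
    write.csv(scored[c("subject_id", "trial", "stimulus_id", "true_category",
                       "correct", "discounted", "relative_accuracy", "confidence")],
              op("accuracy.csv"), row.names = FALSE)
  }

  emg_res <- NULL
  if (!is.null(emg)) {
    emg_res <- run_stage("preprocess_emg", preprocess_emg(
      emg, stimuli = res$design$stimuli, z_threshold = config$z_threshold,
      band = config$filter$band, notch = config$filter$notch,
      order = config$filter$order))
    if (!is.null(emg_res)) {
      write.csv(emg_res$trial_avg, op("emg_trialavg.csv"), row.names = FALSE)
      write.csv(emg_res$cat_avg, op("emg_catavg.csv"), row.names = FALSE)
    }
  }

  meta <- run_stage("metacognition", {
    mc <- compute_metacognition(scored)
    mc$lsas_total <- qn$lsas_total[match(mc$subject_id, qn$subject_id)]
    mc$aq_total <- qn$aq_total[match(mc$subject_id, qn$subject_id)]
    mc
  })
  mc_corr <- NULL
  if (!is.null(meta)) {
    write.csv(meta, op("metacog.csv"), row.names = FALSE)
    mc_corr <- run_stage("metacog_correlations", {
      ok <- !is.na(meta$auroc2)
      list(lsas = metacog_trait_correlation(meta$lsas_total[ok], meta$auroc2[ok],
                                            config$mahalanobis_alpha),
           aq = metacog_trait_correlation(meta$aq_total[ok], meta$auroc2[ok],
                                          config$mahalanobis_alpha))
    })
    if (!is.null(mc_corr))
      jsonlite::write_json(mc_corr, op("metacog_corr.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  models <- run_stage("models", {
    out <- list()
    for (tr in c("lsas", "aq")) {
      tz <- qn[[paste0(tr, "_z")]]
      out[[paste0(toupper(tr), "_x_CATEGORY__accuracy")]] <-
        fit_trait_category_model(scored, tz, "accuracy", nAGQ = config$nAGQ)
      out[[paste0(toupper(tr), "_x_CATEGORY__confidence")]] <-
        fit_trait_category_model(scored, tz, "confidence")
      if (!is.null(emg_res)) {
        for (emo in c("anger", "happiness", "sadness", "fear")) {
          out[[paste0(toupper(tr), "_x_EMG__", emo, "_accuracy")]] <-
            fit_emg_accuracy(scored, emg_res$trial_avg, emo, tz, nAGQ = config$nAGQ)
        }
        for (m in c("corrugator", "zygomaticus")) {
          ca <- emg_res$cat_avg[emg_res$cat_avg$muscle == m, ]
          out[[paste0(toupper(tr), "_x_CATEGORY__", m, "_catavg")]] <-
            fit_lm_category_emg(ca, tz, n_boot = config$n_boot,
                                seed = child_seed(config$seed, paste0("boot", m, tr)))
        }
      }
    }
    out
  })
  if (!is.null(models)) {
    for (nm in names(models)) {
      cf <- models[[nm]]$coefficients
      write.csv(cf, op(paste0("model_", nm, ".csv")), row.names = FALSE)
    }
  }

  run_stage("report", .write_report(op("report.md"), scored, qn, meta, mc_corr, models))
  res <- c(res, list(questionnaires = qn, scored = scored, emg = emg_res,
                     metacog = meta, metacog_corr = mc_corr, models = models,
                     status = status))
  invisible(res)
}

.write_report <- function(path, scored, qn, meta, mc_corr, models) {
  ln <- c("# Pipeline report", "")
  if (!is.null(scored)) {
    acc <- tapply(scored$correct, scored$true_category, mean, na.rm = TRUE)
    conf <- tapply(scored$confidence, scored$true_category, mean)
    ln <- c(ln, "## Per-category accuracy and confidence", "",
            "| category | accuracy | confidence |", "|---|---|---|",
            sprintf("| %s | %.3f | %.1f |", names(acc), acc,
                    conf[names(acc)]), "")
  }
  if (!is.null(mc_corr)) {
    ln <- c(ln, "## AUROC2-trait correlations", "",
            sprintf("- LSAS: r = %.3f, t(%d) = %.3f, p = %.4f (%d excluded)",
                    mc_corr$lsas$pearson$estimate, mc_corr$lsas$pearson$df,
                    mc_corr$lsas$pearson$statistic, mc_corr$lsas$pearson$p.value,
                    mc_corr$lsas$n_excluded),
            sprintf("- AQ: r = %.3f, t(%d) = %.3f, p = %.4f (%d excluded)",
                    mc_corr$aq$pearson$estimate, mc_corr$aq$pearson$df,
                    mc_corr$aq$pearson$statistic, mc_corr$aq$pearson$p.value,
                    mc_corr$aq$n_excluded), "")
  }
  if (!is.null(models)) {
    for (nm in names(models)) {
      cf <- models[[nm]]$coefficients
      ln <- c(ln, paste0("## Model ", nm), "",
              paste0("| ", paste(names(cf), collapse = " | "), " |"),
              paste0("|", paste(rep("---", ncol(cf)), collapse = "|"), "|"),
              apply(cf, 1L, function(r) paste0("| ", paste(
                vapply(r, function(x) {
                  xx <- suppressWarnings(as.numeric(x))
                  if (is.na(xx)) as.character(x) else sprintf("%.4g", xx)
                }, character(1L)), collapse = " | "), " |")), "")
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess-emg`, `score`, `metacog`, `fit`,
#' `report`, `run-all`; flags `--config`, `--seed`, `--out`, `--keep-going`.
#' Installed as `inst/cli/mimicog.R`; run with
#' `Rscript -e 'mimicog::mimicog_cli()' run-all --seed 1 --out out/`.
#'
#' @param args command-line arguments (default: from the process).
#' @return exit status, invisibly (0 = all stages ok).
#' @export
mimicog_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "preprocess-emg", "score", "metacog", "fit",
            "report", "run-all", "validate")
  cmd <- if (length(args) && args[1L] %in% cmds) args[1L] else "run-all"
  get_flag <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cfg_path <- get_flag("--config")
  seed <- as.integer(get_flag("--seed", "1"))
  out <- get_flag("--out", "mimicog_out")
  keep <- "--keep-going" %in% args
  config <- if (!is.null(cfg_path)) read_config(cfg_path, seed = seed, out_dir = out)
            else pipeline_config(seed = seed, out_dir = out)
  if (cmd == "validate") {
    rep <- validate_inputs(list(ratings = get_flag("--ratings"),
                                emg_raw = get_flag("--emg"),
                                traits = get_flag("--traits")))
    print(rep)
    return(invisible(as.integer(length(rep$violations) > 0)))
  }
  ## individual stage commands run the pipeline up to the requested stage;
  ## stages are cheap relative to model fitting, which only 'fit'/'run-all'
  ## trigger.
  if (cmd %in% c("simulate", "preprocess-emg", "score", "metacog")) {
    sim <- simulate_study(config$n_subjects, config$effects, config$seed,
                          emg = config$emg_mode)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(sim$ratings$ratings, file.path(config$out_dir, "ratings.csv"),
              row.names = FALSE)
    write.csv(sim$traits, file.path(config$out_dir, "traits.csv"), row.names = FALSE)
    if (cmd == "simulate") return(invisible(0L))
    if (cmd == "preprocess-emg") {
      pre <- preprocess_emg(sim$emg, sim$design$stimuli, config$z_threshold)
      write.csv(pre$trial_avg, file.path(config$out_dir, "emg_trialavg.csv"),
                row.names = FALSE)
      return(invisible(0L))
    }
    scored <- score_ratings(sim$ratings$ratings)
    write.csv(scored, file.path(config$out_dir, "accuracy.csv"), row.names = FALSE)
    if (cmd == "score") return(invisible(0L))
    mc <- compute_metacognition(scored)
    write.csv(mc, file.path(config$out_dir, "metacog.csv"), row.names = FALSE)
    return(invisible(0L))
  }
  res <- run_pipeline(config, keep_going = keep)
  invisible(as.integer(any(grepl("^failed", res$status))))
}
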