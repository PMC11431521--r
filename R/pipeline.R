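# End-to-end orchestration: simulate (or load) a cohort, expand the
# GAGome, filter by detectability, screen features, fit the two scores,
# run the combined test, and report.

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. The configuration is
#' fully serializable; [run_pipeline()] archives it (with an MD5 hash)
#' alongside its outputs.
#'
#' @param sim_params [default_sim_params()] object, or `NULL` when reading
#'   from files.
#' @param samples_csv,gagome_csv Input paths (used when `sim_params` is
#'   `NULL`).
#' @param lod Detectability limit, ug/mL.
#' @param detectable_override Optional character vector forcing the
#'   detectable set (bypasses the median filter).
#' @param score_features GAGome score predictors; the study's score uses
#'   the absolute 0S CS concentration and the 4S CS mass fraction.
#' @param prior,mcmc,rope Bayesian model settings.
#' @param min_spec_gagome,min_spec_cfdna Specificity floors of the
#'   combined pathway.
#' @param bootstrap_B,bootstrap_seed Bootstrap settings.
#' @param seed Global seed; stage seeds derive from it.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_params = default_sim_params(),
                            samples_csv = NULL, gagome_csv = NULL,
                            lod = 0.1,
                            detectable_override = NULL,
                            score_features = c("0S CS", "4S CS fraction"),
                            prior = prior_spec(),
                            mcmc = mcmc_config(),
                            rope = rope_spec(),
                            min_spec_gagome = 0.95,
                            min_spec_cfdna = 1.0,
                            bootstrap_B = 5000L,
                            bootstrap_seed = 1L,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(
    sim_params = sim_params, samples_csv = samples_csv, gagome_csv = gagome_csv,
    lod = lod, detectable_override = detectable_override,
    score_features = score_features,
    prior = prior, mcmc = mcmc, rope = rope,
    min_spec_gagome = min_spec_gagome, min_spec_cfdna = min_spec_cfdna,
    bootstrap_B = as.integer(bootstrap_B),
    bootstrap_seed = as.integer(bootstrap_seed),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

# internal: stable hash of the configuration (MD5 of its canonical JSON);
# the output directory is not part of the analysis and is excluded
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.serializable(cfg), tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

.serializable <- function(x) {
  if (is.list(x)) return(lapply(x, .serializable))
  if (is.matrix(x)) return(as.data.frame(x))
  x
}

#' Run the full GAGome + cfDNA analysis pipeline
#'
#' Stages: (1) simulate the cohort from `config$sim_params` (or read the
#' CSVs); (2) expand the 39-feature GAGome; (3) apply the plasma
#' detectability filter and select the analysis features; (4) run the
#' covariate-adjusted (batch + sample age) Bayesian equivalence screen
#' over them; (5) fit the GAGome logistic score on the batch-normalized
#' score features and bootstrap its AUC / sensitivity at the GAGome
#' specificity floor; (6) fit the cfDNA logistic score (log concentration
#' + variant count) on the samples with complete cfDNA data; (7) run the
#' sequential combined test over the samples with any cfDNA measurement,
#' treating insufficient ones as cfDNA-negative, and stratify sensitivity
#' by stage. When no sample has cfDNA data the cfDNA/combined stages are
#' skipped with a logged notice. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return List of class `pipeline_result`: `config`, `config_hash`,
#'   `samples`, `features`, `detectability`, `analysis_features`,
#'   `screen`, `gagome_model`, `cfdna_model`, `scores`, `decisions`,
#'   `metrics`. If `config$out_dir` is set, also writes `metrics.json`,
#'   `equivalence.csv`, `decisions.csv`, `scores.csv`, `config.json` and
#'   `report.md` there.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[gagdx] ", ...)
  hash <- .config_hash(config)

  # -- data
  if (!is.null(config$sim_params)) {
    say("simulating cohort (seed ", config$sim_params$seed, ")")
    cohort <- simulate_cohort(config$sim_params)
  } else {
    if (is.null(config$samples_csv) || is.null(config$gagome_csv)) {
      stop("stage data: either sim_params or both CSV paths are required",
           call. = FALSE)
    }
    say("reading cohort from ", config$samples_csv)
    cohort <- list(
      samples = tibble::as_tibble(utils::read.csv(config$samples_csv,
                                                  check.names = FALSE,
                                                  stringsAsFactors = FALSE)),
      gagome = read_gagome_csv(config$gagome_csv)
    )
  }
  samples <- cohort$samples
  say("cohort: ", nrow(samples), " samples (",
      sum(samples$group == "case"), " cases)")

  # -- features
  features <- expand_features(cohort$gagome)
  say("expanded ", ncol(features) - 1, " GAGome features")

  # -- detectability & selection
  det <- detectable_features(cohort$gagome, lod = config$lod)
  if (!is.null(config$detectable_override)) {
    det$detectable <- config$detectable_override
    say("detectable set overridden: ",
        paste(det$detectable, collapse = ", "))
  }
  analysis_features <- select_analysis_features(det)
  say(length(det$detectable), " detectable disaccharides -> ",
      length(analysis_features), " analysis features")

  # -- equivalence screen (batch + sample-age adjusted)
  covars <- data.frame(batch = factor(samples$batch),
                       sample_age_months = samples$sample_age_months)
  screen <- equivalence_screen(features, samples$group,
                               feature_names = analysis_features,
                               covariates = covars,
                               prior = config$prior, mcmc = config$mcmc,
                               rope = config$rope)
  say("screen: ", sum(screen$credible), " of ", nrow(screen),
      " features credibly associated")

  # -- GAGome score
  miss_sf <- setdiff(config$score_features, names(features))
  if (length(miss_sf) > 0) {
    stop("stage gagome_score: unknown score feature(s): ",
         paste(miss_sf, collapse = ", "), call. = FALSE)
  }
  Xg <- as.data.frame(lapply(
    stats::setNames(config$score_features, config$score_features),
    function(f) batch_normalize(features[[f]], samples$batch)
  ), check.names = FALSE)
  mc_g <- config$mcmc
  mc_g$seed <- as.integer((as.numeric(config$seed) * 131 + 101) %% 2147483399)
  gagome_model <- fit_logistic_score(Xg, samples$group,
                                     prior = config$prior, mcmc = mc_g)
  gagome_score <- predict_log_odds(gagome_model, Xg)
  gag_boot <- bootstrap_metrics(gagome_score, samples$group,
                                min_spec = config$min_spec_gagome,
                                B = config$bootstrap_B,
                                seed = config$bootstrap_seed)
  say("GAGome score: AUC ", round(gag_boot$metrics$estimate[1], 3))

  scores <- tibble::tibble(
    sample_id = samples$sample_id,
    label = samples$group,
    stage = samples$stage,
    gagome_score = gagome_score,
    cfdna_score = NA_real_,
    cfdna_status = if ("cfdna_status" %in% names(samples)) {
      samples$cfdna_status
    } else "missing"
  )

  metrics <- list(
    config_hash = hash,
    n_samples = nrow(samples),
    n_cases = sum(samples$group == "case"),
    n_controls = sum(samples$group == "control"),
    n_features = ncol(features) - 1L,
    detectable = det$detectable,
    n_analysis_features = length(analysis_features),
    credible_features = screen$feature[screen$credible],
    gagome = list(
      auc = gag_boot$metrics$estimate[1],
      auc_ci = c(gag_boot$metrics$ci_low[1], gag_boot$metrics$ci_high[1]),
      sensitivity = gag_boot$metrics$estimate[2],
      sensitivity_ci = c(gag_boot$metrics$ci_low[2], gag_boot$metrics$ci_high[2]),
      min_spec = config$min_spec_gagome,
      bootstrap_B = gag_boot$B
    )
  )

  # -- cfDNA score + combined test
  cfdna_model <- NULL
  decisions <- NULL
  has_cfdna_cols <- all(c("cfdna_conc", "cfdna_variants", "cfdna_status") %in%
                          names(samples))
  complete_cf <- if (has_cfdna_cols) {
    samples$cfdna_status == "available" & !is.na(samples$cfdna_conc) &
      !is.na(samples$cfdna_variants)
  } else rep(FALSE, nrow(samples))
  if (sum(complete_cf) > 0 &&
      length(unique(samples$group[complete_cf])) == 2) {
    Xc <- data.frame(
      log_cfdna_conc = log(samples$cfdna_conc[complete_cf]),
      cfdna_variants = as.numeric(samples$cfdna_variants[complete_cf])
    )
    mc_c <- config$mcmc
    mc_c$seed <- as.integer((as.numeric(config$seed) * 131 + 102) %% 2147483399)
    cfdna_model <- fit_logistic_score(Xc, samples$group[complete_cf],
                                      prior = config$prior, mcmc = mc_c)
    scores$cfdna_score[complete_cf] <- predict_log_odds(cfdna_model, Xc)
    cf_roc <- roc_auc(scores$cfdna_score[complete_cf],
                      samples$group[complete_cf])
    cf_sens <- sensitivity_at_specificity(scores$cfdna_score[complete_cf],
                                          samples$group[complete_cf],
                                          config$min_spec_cfdna)
    say("cfDNA score (n = ", sum(complete_cf), "): AUC ",
        round(cf_roc$auc, 3))

    eval_idx <- samples$cfdna_status %in% c("available", "insufficient")
    decisions <- combined_test(scores[eval_idx, ],
                               min_spec_cfdna = config$min_spec_cfdna,
                               min_spec_gagome = config$min_spec_gagome)
    g_eval <- .case_indicator(decisions$label)
    comb_sens <- mean(decisions$combined_call[g_eval == 1] == "positive")
    comb_spec <- mean(decisions$combined_call[g_eval == 0] == "negative")
    cf_only_sens <- mean(decisions$cfdna_call[g_eval == 1] == "positive")
    stages_eval <- scores$stage[eval_idx]
    by_stage <- stage_stratified_sensitivity(decisions, stages_eval)
    by_stage_cf <- stage_stratified_sensitivity(decisions, stages_eval,
                                                call = "cfdna_call")
    metrics$cfdna <- list(
      n = sum(complete_cf),
      auc = cf_roc$auc,
      sensitivity = cf_sens$sensitivity,
      min_spec = config$min_spec_cfdna
    )
    metrics$combined <- list(
      n = sum(eval_idx),
      sensitivity = comb_sens,
      specificity = comb_spec,
      cfdna_only_sensitivity = cf_only_sens,
      reclassified_positive = sum(decisions$reclassified_positive),
      reclassified_cases = sum(decisions$reclassified_positive[g_eval == 1]),
      by_stage = by_stage,
      by_stage_cfdna = by_stage_cf,
      cutoffs = as.list(attr(decisions, "cutoffs"))
    )
    say("combined test: sensitivity ", round(comb_sens, 3),
        " at specificity ", round(comb_spec, 3))

    corr <- feature_cfdna_correlation(
      features[config$score_features],
      samples[c("cfdna_conc", "cfdna_variants")]
    )
    metrics$score_feature_cfdna_correlation <- corr
  } else {
    say("no usable cfDNA data; skipping cfDNA score and combined test")
  }

  result <- structure(list(
    config = config, config_hash = hash,
    samples = samples, features = features,
    detectability = det, analysis_features = analysis_features,
    screen = screen, gagome_model = gagome_model, cfdna_model = cfdna_model,
    scores = scores, decisions = decisions, metrics = metrics
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(.serializable(metrics), file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(screen, file.path(dir, "equivalence.csv"),
                     row.names = FALSE)
    .write_csv_full(scores, file.path(dir, "scores.csv"))
    if (!is.null(decisions)) {
      utils::write.csv(decisions, file.path(dir, "decisions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      c(list(config_hash = hash), .serializable(unclass(config))),
      file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
      null = "null", force = TRUE)
    writeLines(render_report(metrics, decisions), file.path(dir, "report.md"))
    say("report bundle written to ", dir)
  }
  result
}

#' Render a human-readable analysis report
#'
#' Markdown summary of a pipeline run: cohort composition, the screened
#' feature verdicts, score performance with bootstrap CIs, per-stage
#' sensitivities and the reclassification accounting.
#'
#' @param metrics Metrics list from [run_pipeline()] (`$metrics`).
#' @param decisions Optional decision tibble from the combined test.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(metrics, decisions = NULL) {
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  out <- c(
    "# GAGome + cfDNA diagnostic analysis",
    "",
    paste0("Configuration hash: `", metrics$config_hash, "`"),
    "",
    "## Cohort"
  )
  if (is.null(metrics$n_samples) || metrics$n_samples == 0) {
    out <- c(out, "", "No samples.")
  } else {
    out <- c(out, "",
             sprintf("- %d samples: %d cases, %d controls",
                     metrics$n_samples, metrics$n_cases, metrics$n_controls))
  }
  out <- c(out, "", "## GAGome features", "",
           sprintf("- %d expanded features; detectable disaccharides: %s",
                   metrics$n_features,
                   if (length(metrics$detectable)) {
                     paste(metrics$detectable, collapse = ", ")
                   } else "none"),
           sprintf("- %d analysis features screened; credible: %s",
                   metrics$n_analysis_features,
                   if (length(metrics$credible_features)) {
                     paste(metrics$credible_features, collapse = ", ")
                   } else "none"))
  g <- metrics$gagome
  out <- c(out, "", "## GAGome score", "",
           sprintf("- AUC %.2f (95%% CI %.2f-%.2f)", g$auc, g$auc_ci[1], g$auc_ci[2]),
           sprintf("- sensitivity %s (95%% CI %s-%s) at minimum %s specificity (B = %d bootstraps)",
                   pct(g$sensitivity), pct(g$sensitivity_ci[1]),
                   pct(g$sensitivity_ci[2]), pct(g$min_spec), g$bootstrap_B))
  if (!is.null(metrics$cfdna)) {
    out <- c(out, "", "## cfDNA score", "",
             sprintf("- n = %d with complete cfDNA data", metrics$cfdna$n),
             sprintf("- AUC %.2f; sensitivity %s at minimum %s specificity",
                     metrics$cfdna$auc, pct(metrics$cfdna$sensitivity),
                     pct(metrics$cfdna$min_spec)))
  }
  if (!is.null(metrics$combined)) {
    cb <- metrics$combined
    out <- c(out, "", "## Combined sequential test", "",
             sprintf("- n = %d evaluated (insufficient cfDNA counted negative)", cb$n),
             sprintf("- sensitivity %s at specificity %s (cfDNA alone: %s)",
                     pct(cb$sensitivity), pct(cb$specificity),
                     pct(cb$cfdna_only_sensitivity)),
             sprintf("- reclassified positive: %d (%d cases)",
                     cb$reclassified_positive, cb$reclassified_cases),
             "", "Per-stage sensitivity (combined | cfDNA alone):", "")
    bs <- cb$by_stage; bc <- cb$by_stage_cfdna
    for (i in seq_len(nrow(bs))) {
      out <- c(out, sprintf("- stage %s (n = %d): %s | %s",
                            bs$stratum[i], bs$n[i],
                            if (bs$defined[i]) pct(bs$sensitivity[i]) else "undefined",
                            if (bc$defined[i]) pct(bc$sensitivity[i]) else "undefined"))
    }
  }
  if (!is.null(decisions)) {
    out <- c(out, "",
             sprintf("Decisions: %d rows, %d combined positive, %d reclassified.",
                     nrow(decisions),
                     sum(decisions$combined_call == "positive"),
                     sum(decisions$reclassified_positive)))
  } else if (is.null(metrics$combined)) {
    out <- c(out, "", "No combined-test decisions (no usable cfDNA data).")
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(render_report(x$metrics, x$decisions), sep = "\n")
  invisible(x)
}
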