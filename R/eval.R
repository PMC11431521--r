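# Diagnostic performance evaluation: ROC/AUC with Mann-Whitney tie
# handling, threshold calibration under a specificity floor, stratified
# bootstrap CIs, the sequential combined cfDNA + GAGome test with its
# specificity budget, stage-stratified sensitivity, rank correlations and
# cohort characteristic tests.

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability: the proportion of case-control
#' pairs where the case scores higher, ties counted 1/2 (computed via
#' midranks). The curve enumerates every candidate cut-off (each unique
#' score and -Inf) under the "positive = strictly above cut-off" rule.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case/control labels.
#' @return List of class `roc_result`: `auc`, `curve` (tibble: cutoff,
#'   specificity, sensitivity), `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels) {
  g <- .case_indicator(labels)
  stopifnot(length(scores) == length(g), !anyNA(scores))
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cutoffs <- c(-Inf, sort(unique(scores)))
  curve <- tibble::tibble(
    cutoff = cutoffs,
    specificity = vapply(cutoffs, function(t) mean(scores[g == 0] <= t), numeric(1)),
    sensitivity = vapply(cutoffs, function(t) mean(scores[g == 1] > t), numeric(1))
  )
  structure(list(auc = auc, curve = curve, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d cases, %d controls)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' Score cut-off attaining a specificity floor
#'
#' Returns the smallest cut-off whose specificity on the controls is at
#' least `min_spec`, under the rule that a sample is positive when its
#' score is strictly above the cut-off. The smallest conformant cut-off
#' maximizes sensitivity subject to the floor; it is always one of the
#' control score values (or `-Inf` when the floor is vacuous).
#'
#' @param scores Numeric scores.
#' @param labels Case/control labels (controls required).
#' @param min_spec Required minimum specificity in (0, 1].
#' @return The cut-off (scalar).
#' @export
threshold_at_specificity <- function(scores, labels, min_spec) {
  g <- .case_indicator(labels)
  stopifnot(length(scores) == length(g), !anyNA(scores),
            min_spec >= 0, min_spec <= 1)
  ctrl <- scores[g == 0]
  if (length(ctrl) == 0) stop("no controls to calibrate on", call. = FALSE)
  cand <- c(-Inf, sort(unique(ctrl)))
  spec <- vapply(cand, function(t) mean(ctrl <= t), numeric(1))
  cand[which(spec >= min_spec)[1]]
}

#' Sensitivity at a specificity floor
#'
#' Calibrates the cut-off with [threshold_at_specificity()] and evaluates
#' the sensitivity of "score strictly above cut-off" on the cases.
#'
#' @inheritParams threshold_at_specificity
#' @return List with `sensitivity`, `specificity` (achieved on controls)
#'   and `cutoff`.
#' @export
sensitivity_at_specificity <- function(scores, labels, min_spec) {
  g <- .case_indicator(labels)
  if (sum(g == 1) == 0 || sum(g == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  cut <- threshold_at_specificity(scores, labels, min_spec)
  list(sensitivity = mean(scores[g == 1] > cut),
       specificity = mean(scores[g == 0] <= cut),
       cutoff = cut)
}

# internal: seed-scoped RNG (save/restore global .Random.seed)
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Bootstrap CIs for AUC and sensitivity at fixed specificity
#'
#' Stratified bootstrap: cases and controls are resampled separately with
#' replacement, preserving the group sizes, and AUC plus sensitivity at
#' the specificity floor are recomputed per replicate (the cut-off is
#' recalibrated inside each replicate). Confidence intervals are the
#' 2.5/97.5 percentiles of the bootstrap distributions. Deterministic
#' under `seed`.
#'
#' @inheritParams threshold_at_specificity
#' @param B Number of bootstrap replicates (study default 5000).
#' @param seed Integer seed.
#' @return List of class `bootstrap_summary`: `B`, `seed`, `metrics`
#'   (tibble: metric, estimate, ci_low, ci_high), and `replicates`
#'   (B x 2 matrix of per-replicate values).
#' @export
bootstrap_metrics <- function(scores, labels, min_spec, B = 5000L, seed = 1L) {
  stopifnot(B >= 1)
  g <- .case_indicator(labels)
  case_idx <- which(g == 1); ctrl_idx <- which(g == 0)
  if (length(case_idx) == 0 || length(ctrl_idx) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  point_auc <- roc_auc(scores, g)$auc
  point_sens <- sensitivity_at_specificity(scores, g, min_spec)$sensitivity
  reps <- .with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      i <- c(sample(case_idx, replace = TRUE), sample(ctrl_idx, replace = TRUE))
      sc <- scores[i]; gb <- g[i]
      c(auc = roc_auc(sc, gb)$auc,
        sensitivity = sensitivity_at_specificity(sc, gb, min_spec)$sensitivity)
    }, c(auc = 0, sensitivity = 0)))
  })
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  metrics <- tibble::tibble(
    metric = c("auc", "sensitivity"),
    estimate = c(point_auc, point_sens),
    ci_low = ci[1, ],
    ci_high = ci[2, ]
  )
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 min_spec = min_spec, metrics = metrics, replicates = reps),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap (B = %d, min specificity %.0f%%):\n",
              x$B, 100 * x$min_spec))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %s: %.3f (95%% CI %.3f-%.3f)\n",
                m$metric[i], m$estimate[i], m$ci_low[i], m$ci_high[i]))
  }
  invisible(x)
}

#' Sequential combined cfDNA + GAGome test
#'
#' Implements the combined diagnostic pathway with its specificity
#' budget: (1) calibrate the cfDNA cut-off at a minimum 100% specificity
#' on the calibration controls with an available cfDNA score; (2)
#' calibrate the GAGome cut-off at a minimum 95% specificity on all
#' controls; (3) call each score positive when strictly above its
#' cut-off, treating samples whose cfDNA measurement is insufficient or
#' missing as cfDNA-negative; (4) call the combined test positive when at
#' least one sub-test is positive; (5) flag cfDNA-negative / GAGome-
#' positive samples as "reclassified positive".
#'
#' @param data Data frame with columns `sample_id`, `label`
#'   (case/control), `gagome_score` (required for every sample),
#'   `cfdna_score` (NA allowed) and `cfdna_status` (`"available"`,
#'   `"insufficient"` or `"missing"`).
#' @param min_spec_cfdna,min_spec_gagome Specificity floors (1.00, 0.95).
#' @return Tibble of per-sample decisions (`cfdna_call`, `gagome_call`,
#'   `combined_call`, `reclassified_positive`) with the calibrated
#'   cut-offs in attribute `"cutoffs"`.
#' @export
combined_test <- function(data, min_spec_cfdna = 1.0, min_spec_gagome = 0.95) {
  req <- c("sample_id", "label", "gagome_score", "cfdna_score", "cfdna_status")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    stop("combined_test input lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- .case_indicator(data$label)
  if (sum(g == 0) == 0) stop("no controls to calibrate on", call. = FALSE)
  if (anyNA(data$gagome_score)) {
    stop("every sample needs a GAGome score", call. = FALSE)
  }
  has_cf <- data$cfdna_status == "available" & !is.na(data$cfdna_score)
  if (!any(has_cf & g == 0)) {
    stop("no controls with an available cfDNA score to calibrate on",
         call. = FALSE)
  }
  cut_cf <- threshold_at_specificity(data$cfdna_score[has_cf], g[has_cf],
                                     min_spec_cfdna)
  cut_gag <- threshold_at_specificity(data$gagome_score, g, min_spec_gagome)
  cfdna_call <- ifelse(has_cf & data$cfdna_score > cut_cf, "positive", "negative")
  gagome_call <- ifelse(data$gagome_score > cut_gag, "positive", "negative")
  combined_call <- ifelse(cfdna_call == "positive" | gagome_call == "positive",
                          "positive", "negative")
  out <- tibble::tibble(
    sample_id = data$sample_id,
    label = data$label,
    cfdna_call = cfdna_call,
    gagome_call = gagome_call,
    combined_call = combined_call,
    reclassified_positive = cfdna_call == "negative" & gagome_call == "positive"
  )
  attr(out, "cutoffs") <- c(cfdna = cut_cf, gagome = cut_gag)
  out
}

#' Stage-stratified sensitivity
#'
#' Sensitivity of a call column among cases, by IASLC stage stratum
#' (I, II-III pooled, IV).
#'
#' @param decisions Decision tibble (from [combined_test()] or any table
#'   with `label` and the call column).
#' @param stages Character vector of stages (`"I"`, `"II"`, `"III"`,
#'   `"IV"`, NA for controls), aligned with `decisions`.
#' @param call Name of the call column (default `"combined_call"`).
#' @return Tibble: `stratum`, `n`, `positive`, `sensitivity` (proportion;
#'   `NA` with a `defined = FALSE` flag for empty strata).
#' @export
stage_stratified_sensitivity <- function(decisions, stages,
                                         call = "combined_call") {
  stopifnot(length(stages) == nrow(decisions), call %in% names(decisions))
  g <- .case_indicator(decisions$label)
  stratum <- rep(NA_character_, length(stages))
  stratum[stages %in% "I"] <- "I"
  stratum[stages %in% c("II", "III")] <- "II-III"
  stratum[stages %in% "IV"] <- "IV"
  pos <- decisions[[call]] == "positive"
  rows <- lapply(c("I", "II-III", "IV"), function(s) {
    idx <- which(g == 1 & stratum %in% s)
    tibble::tibble(
      stratum = s,
      n = length(idx),
      positive = sum(pos[idx]),
      sensitivity = if (length(idx) > 0) mean(pos[idx]) else NA_real_,
      defined = length(idx) > 0
    )
  })
  do.call(rbind, rows)
}

#' Rank correlation between GAGome features and cfDNA measures
#'
#' Spearman rank correlation (two-sided asymptotic test) between each
#' feature and each cfDNA measure, over pairwise-complete observations.
#' Used to verify that the GAGome score's inputs carry information
#' independent of the cfDNA measurements.
#'
#' @param features Data frame of feature columns.
#' @param cfdna Data frame of cfDNA measure columns (e.g. `cfdna_conc`,
#'   `cfdna_variants`), aligned by row.
#' @return Tibble: `feature`, `measure`, `n`, `rho`, `p_value`.
#' @export
feature_cfdna_correlation <- function(features, cfdna) {
  stopifnot(nrow(features) == nrow(cfdna))
  fn <- setdiff(names(features), "sample_id")
  mn <- setdiff(names(cfdna), "sample_id")
  rows <- list()
  for (f in fn) {
    for (m in mn) {
      ok <- !is.na(features[[f]]) & !is.na(cfdna[[m]])
      if (sum(ok) < 3) {
        stop("fewer than 3 complete pairs for ", f, " vs ", m, call. = FALSE)
      }
      ct <- suppressWarnings(
        stats::cor.test(features[[f]][ok], cfdna[[m]][ok],
                        method = "spearman", exact = FALSE)
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = f, measure = m, n = sum(ok),
        rho = unname(ct$estimate), p_value = ct$p.value
      )
    }
  }
  do.call(rbind, rows)
}

#' Cohort characteristic tests
#'
#' Case-control comparisons of clinical characteristics: Pearson
#' chi-square tests (no continuity correction; missing values excluded)
#' for categorical variables and two-sample t-tests for continuous ones
#' (unequal-variance Welch form by default; `t_variant = "student"` for
#' the pooled-variance form).
#'
#' @param samples Data frame with a `group` column (case/control).
#' @param continuous,categorical Column names to test.
#' @param t_variant `"welch"` (default) or `"student"`.
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p_value`.
#' @export
cohort_characteristics <- function(samples,
                                   continuous = "age_years",
                                   categorical = c("sex", "smoking"),
                                   t_variant = c("welch", "student")) {
  t_variant <- match.arg(t_variant)
  g <- .case_indicator(samples$group)
  if (sum(g == 1) == 0 || sum(g == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  rows <- list()
  for (v in continuous) {
    tt <- stats::t.test(samples[[v]][g == 1], samples[[v]][g == 0],
                        var.equal = (t_variant == "student"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = paste0("t (", t_variant, ")"),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  for (v in categorical) {
    ok <- !is.na(samples[[v]])
    tab <- table(samples[[v]][ok], samples$group[ok])
    rows[[length(rows) + 1]] <- chisq_from_table(tab)
    rows[[length(rows)]]$variable <- v
  }
  do.call(rbind, rows)
}

#' Pearson chi-square test from a contingency table
#'
#' Pearson chi-square with no continuity correction. For a
#' 3 x 2 table (df = 2) the p-value equals `exp(-statistic / 2)` exactly.
#'
#' @param tab A contingency matrix/table of counts.
#' @return One-row tibble: `variable`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
chisq_from_table <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("expected cell count of zero; cannot run chi-square test",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    variable = NA_character_, test = "chi-square",
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value
  )
}
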