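# Synthetic case-control cohort generator. Stands in for the (non-public)
# clinical data: lognormal disaccharide concentrations with case shifts on
# 0S CS (up) and 4S CS (down), additive batch and sample-age effects on the
# log scale, stage-dependent cfDNA elevation in cases, and availability
# masks matching the study (81 with cfDNA concentration, 74 with variant
# counts, 7 insufficient). GAGome and cfDNA draws are independent by
# construction.

# internal: run expr under a component-specific seed derived from `seed`,
# restoring the caller's RNG state afterwards. Components use disjoint
# offsets so adding one never perturbs another's draws.
.with_substream <- function(seed, component, expr) {
  derived <- (as.numeric(seed) * 48271 + component * 16807) %% 2147483399
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  force(expr)
}

#' Default synthetic cohort parameters
#'
#' Parameters emulating the clinical study's structure: 85 cases with
#' stage distribution I/II/III/IV = 9/6/18/52 and 28 controls; control
#' log-concentrations calibrated so that only 0S CS and 4S CS have median
#' above the 0.1 ug/mL detectability limit; a standardized case increase
#' in 0S CS and decrease in 4S CS (log scale); two experimental batches
#' and a sample-age drift acting additively on log concentration; cfDNA
#' concentration and variant counts elevated in cases with an effect that
#' grows with IASLC stage, drawn independently of the GAGome; and cfDNA
#' availability masks of 81 / 74 / 7 samples.
#'
#' @param n_case,n_control Group sizes.
#' @param stage_counts Named integer vector of cases per stage
#'   (must sum to `n_case`).
#' @param delta_0S_CS,delta_4S_CS Case effect sizes for the two
#'   cancer-associated disaccharides, in units of the log-scale SD
#'   (positive = higher in cases).
#' @param batch_shift Additive log-scale shift of batch 2 (technical).
#' @param batch_prob Probability of assignment to batch 2.
#' @param sample_age_slope Log-scale drift per month of sample age.
#' @param sample_age_range Range (months) for uniform sample ages.
#' @param lod Limit of detection, ug/mL.
#' @param cfdna_log_mean,cfdna_log_sd Control cfDNA log-concentration
#'   (concentration in ng/mL).
#' @param cfdna_stage_shift Named log-scale case shifts per stage.
#' @param variants_mu_control,variants_mu_stage,variants_size Negative-
#'   binomial means (controls; named per-stage for cases) and dispersion
#'   for cfDNA variant counts.
#' @param n_with_cfdna,n_with_ngs Availability: samples with cfDNA
#'   concentration, and the subset with variant calls; the difference is
#'   reported as "insufficient".
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A list of class `sim_params`.
#' @export
default_sim_params <- function(n_case = 85L,
                               n_control = 28L,
                               stage_counts = c(I = 9L, II = 6L, III = 18L, IV = 52L),
                               delta_0S_CS = 0.6,
                               delta_4S_CS = -0.6,
                               batch_shift = 0.15,
                               batch_prob = 0.5,
                               sample_age_slope = -0.003,
                               sample_age_range = c(6, 48),
                               lod = 0.1,
                               cfdna_log_mean = log(6),
                               cfdna_log_sd = 0.5,
                               cfdna_stage_shift = c(I = 0.1, II = 0.45, III = 0.75, IV = 1.1),
                               variants_mu_control = 0.3,
                               variants_mu_stage = c(I = 0.6, II = 1.8, III = 3, IV = 5),
                               variants_size = 1.2,
                               n_with_cfdna = 81L,
                               n_with_ngs = 74L,
                               seed = 1L) {
  panel <- gag_panel()
  # control medians: 0S CS and 4S CS well above the 0.1 ug/mL LOD (4S CS is
  # the dominant free plasma CS), everything else trace-level below it
  log_mean <- stats::setNames(rep(log(0.02), nrow(panel)), panel$name)
  log_mean["0S CS"] <- log(1.4)
  log_mean["4S CS"] <- log(2.2)
  log_mean["6S CS"] <- log(0.05)
  log_mean["HA 0S"] <- log(0.04)
  log_sd <- stats::setNames(rep(0.6, nrow(panel)), panel$name)
  log_sd[c("0S CS", "4S CS")] <- 0.35
  p <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    stage_counts = stage_counts,
    log_mean = log_mean, log_sd = log_sd,
    delta_0S_CS = delta_0S_CS, delta_4S_CS = delta_4S_CS,
    batch_shift = batch_shift, batch_prob = batch_prob,
    sample_age_slope = sample_age_slope, sample_age_range = sample_age_range,
    lod = lod,
    cfdna_log_mean = cfdna_log_mean, cfdna_log_sd = cfdna_log_sd,
    cfdna_stage_shift = cfdna_stage_shift,
    variants_mu_control = variants_mu_control,
    variants_mu_stage = variants_mu_stage,
    variants_size = variants_size,
    n_with_cfdna = as.integer(n_with_cfdna),
    n_with_ngs = as.integer(n_with_ngs),
    n_insufficient = as.integer(n_with_cfdna) - as.integer(n_with_ngs),
    seed = as.integer(seed)
  )
  .validate_sim_params(p)
  structure(p, class = "sim_params")
}

.validate_sim_params <- function(p) {
  if (sum(p$stage_counts) != p$n_case) {
    stop("stage_counts must sum to n_case (", sum(p$stage_counts), " != ",
         p$n_case, ")", call. = FALSE)
  }
  if (!all(names(p$stage_counts) == c("I", "II", "III", "IV"))) {
    stop("stage_counts must be named I, II, III, IV", call. = FALSE)
  }
  if (p$n_with_ngs > p$n_with_cfdna) {
    stop("n_with_ngs cannot exceed n_with_cfdna", call. = FALSE)
  }
  n <- p$n_case + p$n_control
  if (p$n_with_cfdna > n) stop("n_with_cfdna exceeds cohort size", call. = FALSE)
  if (any(p$log_sd <= 0) || p$cfdna_log_sd <= 0) {
    stop("all SDs must be > 0", call. = FALSE)
  }
  invisible(p)
}

#' Simulate a synthetic case-control cohort
#'
#' Draws a cohort under the generative model of [default_sim_params()]:
#' clinical covariates loosely matching the published cohort table
#' (per-group age, sex and smoking marginals), lognormal GAGome
#' concentrations with case shifts applied to 0S CS and 4S CS and
#' additive batch / sample-age effects on the log scale, and cfDNA
#' concentration (lognormal) and variant counts (negative binomial) with
#' stage-dependent case shifts, drawn independently of the GAGome.
#' Availability masks are assigned at random: `n_with_cfdna` samples get
#' a concentration, `n_with_ngs` of those also get a variant count, and
#' the remainder are flagged `insufficient`. Bit-identical under a fixed
#' `params$seed`.
#'
#' @param params A `sim_params` object.
#' @return List with `samples` (tibble of per-sample metadata and cfDNA
#'   measurements; controls have `stage = NA`, unavailable cfDNA values
#'   are `NA` with `cfdna_status` one of `"available"`, `"insufficient"`,
#'   `"missing"`), `gagome` (tibble, `sample_id` + 17 canonical
#'   disaccharide concentrations), and `truth` (the realized generating
#'   parameters).
#' @export
simulate_cohort <- function(params = default_sim_params()) {
  .validate_sim_params(params)
  p <- params
  n <- p$n_case + p$n_control
  ref <- study_cohort_counts()
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(c("case", "control"), c(p$n_case, p$n_control))
  stage <- c(rep(names(p$stage_counts), p$stage_counts), rep(NA_character_, p$n_control))

  covar <- .with_substream(p$seed, 1L, {
    age <- ifelse(group == "case",
                  stats::rnorm(n, ref$age$case["mean"], ref$age$case["sd"]),
                  stats::rnorm(n, ref$age$control["mean"], ref$age$control["sd"]))
    age <- round(pmin(pmax(age, 30), 95), 1)
    p_female <- ifelse(group == "case",
                       ref$sex["female", "case"] / p$n_case,
                       ref$sex["female", "control"] / p$n_control)
    sex <- ifelse(stats::runif(n) < p_female, "female", "male")
    smoke_lv <- rownames(ref$smoking)
    smoking <- character(n)
    for (g in c("case", "control")) {
      idx <- group == g
      pr <- ref$smoking[, g] / sum(ref$smoking[, g])
      smoking[idx] <- sample(smoke_lv, sum(idx), replace = TRUE, prob = pr)
    }
    smoking[smoking == "missing"] <- NA_character_
    batch <- ifelse(stats::runif(n) < p$batch_prob, "B2", "B1")
    sample_age <- round(stats::runif(n, p$sample_age_range[1], p$sample_age_range[2]), 1)
    list(age = age, sex = sex, smoking = smoking, batch = batch,
         sample_age = sample_age)
  })

  gag <- .with_substream(p$seed, 2L, {
    panel <- gag_panel()
    m <- matrix(NA_real_, n, nrow(panel), dimnames = list(sample_id, panel$name))
    is_case <- group == "case"
    batch_eff <- ifelse(covar$batch == "B2", p$batch_shift, 0)
    age_eff <- p$sample_age_slope * covar$sample_age
    for (d in panel$name) {
      mu <- p$log_mean[d] + batch_eff + age_eff
      if (d == "0S CS") mu <- mu + is_case * p$delta_0S_CS * p$log_sd[d]
      if (d == "4S CS") mu <- mu + is_case * p$delta_4S_CS * p$log_sd[d]
      m[, d] <- exp(stats::rnorm(n, mu, p$log_sd[d]))
    }
    m
  })

  cfdna <- .with_substream(p$seed, 3L, {
    shift <- numeric(n)
    mu_var <- rep(p$variants_mu_control, n)
    is_case <- group == "case"
    shift[is_case] <- p$cfdna_stage_shift[stage[is_case]]
    mu_var[is_case] <- p$variants_mu_stage[stage[is_case]]
    conc <- exp(stats::rnorm(n, p$cfdna_log_mean + shift, p$cfdna_log_sd))
    variants <- stats::rnbinom(n, size = p$variants_size, mu = mu_var)
    list(conc = conc, variants = variants)
  })

  avail <- .with_substream(p$seed, 4L, {
    with_conc <- sample(n, p$n_with_cfdna)
    with_ngs <- sample(with_conc, p$n_with_ngs)
    status <- rep("missing", n)
    status[with_conc] <- "insufficient"
    status[with_ngs] <- "available"
    status
  })

  cfdna_conc <- ifelse(avail == "missing", NA_real_, cfdna$conc)
  cfdna_variants <- ifelse(avail == "available", cfdna$variants, NA_integer_)

  samples <- tibble::tibble(
    sample_id = sample_id,
    group = group,
    stage = stage,
    age_years = covar$age,
    sex = covar$sex,
    smoking = covar$smoking,
    batch = covar$batch,
    sample_age_months = covar$sample_age,
    cfdna_conc = cfdna_conc,
    cfdna_variants = as.integer(cfdna_variants),
    cfdna_status = avail
  )
  gagome <- tibble::as_tibble(cbind(
    tibble::tibble(sample_id = sample_id),
    tibble::as_tibble(as.data.frame(gag, check.names = FALSE))
  ))
  truth <- list(
    params = unclass(p),
    effects = list(
      log_shift_0S_CS = p$delta_0S_CS * p$log_sd[["0S CS"]],
      log_shift_4S_CS = p$delta_4S_CS * p$log_sd[["4S CS"]],
      batch_shift = p$batch_shift,
      sample_age_slope = p$sample_age_slope,
      cfdna_stage_shift = as.list(p$cfdna_stage_shift),
      variants_mu_stage = as.list(p$variants_mu_stage)
    )
  )
  list(samples = samples, gagome = gagome, truth = truth)
}

#' Write / read a simulated cohort
#'
#' Serializes a cohort to `samples.csv`, `gagome.csv` (CSV-style column
#' names) and `truth.json` in `dir`; missing values become empty cells.
#' Doubles are written at full precision so that `read_cohort(write_cohort(x))`
#' reproduces `x` exactly.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_csv_full(cohort$samples, file.path(dir, "samples.csv"))
  write_gagome_csv(cohort$gagome, file.path(dir, "gagome.csv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()`: list with `samples`, `gagome` and (if present)
#'   `truth`.
#' @export
read_cohort <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"), check.names = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = c(sample_id = "character",
                                            group = "character",
                                            stage = "character",
                                            sex = "character",
                                            smoking = "character",
                                            batch = "character",
                                            cfdna_status = "character"))
  if (nrow(samples) > 0) {
    samples$cfdna_variants <- as.integer(samples$cfdna_variants)
    for (col in c("stage", "smoking")) {
      samples[[col]][!is.na(samples[[col]]) & samples[[col]] == ""] <- NA_character_
    }
  }
  gagome <- read_gagome_csv(file.path(dir, "gagome.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  list(samples = tibble::as_tibble(samples), gagome = gagome, truth = truth)
}
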