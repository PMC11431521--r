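# Bayesian models behind the equivalence screen and the diagnostic scores.
# Both the Gaussian group-difference model and the Bernoulli-logit score
# model place a Student-t(df = 7, location = 0, scale = 2) prior on the
# intercept and every coefficient; the Gaussian model adds a half-t prior
# on the residual scale. Models are sampled with JAGS (rjags), seeded per
# chain for exact reproducibility, and every fit carries split R-hat / ESS
# diagnostics (see mcmc_diagnostics()).

#' Prior specification for all model coefficients
#'
#' A Student-t prior centered on 0 with 7 degrees of freedom and scale 2,
#' applied to the intercept and every coefficient of both the linear
#' equivalence models and the logistic score models.
#'
#' @param df Degrees of freedom (> 0).
#' @param location Center of the prior.
#' @param scale Scale (> 0).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(df = 7, location = 0, scale = 2) {
  stopifnot(df > 0, scale > 0)
  structure(list(df = df, location = location, scale = scale),
            class = "prior_spec")
}

#' MCMC sampling configuration
#'
#' Defaults follow the study's sampler settings: four chains of 10,000
#' iterations with a warmup of 5,000, leaving 5,000 retained draws per
#' chain. Reduced profiles (fewer/shorter chains) are appropriate for
#' simulation studies as long as the convergence gates still pass.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Total iterations per chain.
#' @param warmup Warmup iterations per chain (< `iterations`); discarded.
#' @param seed Integer seed; per-chain RNG seeds derive from it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 10000L, warmup = 5000L,
                        seed = 1L) {
  stopifnot(chains >= 2, warmup < iterations, warmup >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Region of practical equivalence (ROPE) specification
#'
#' The ROPE is the interval of standardized group differences considered
#' practically equivalent to zero, by default \[-0.1, 0.1\] (a negligible
#' effect size). A feature is credibly associated with case-control status
#' when its 95% posterior interval excludes zero and at most 10% of the
#' in-interval posterior mass lies inside the ROPE.
#'
#' @param interval Length-2 numeric ROPE bounds.
#' @param ci_level Posterior interval level (default 0.95).
#' @param max_rope_overlap Maximum tolerated in-interval ROPE mass (0.10).
#' @param interval_type `"eti"` for the equal-tailed quantile interval
#'   (default) or `"hdi"` for the highest-density interval.
#' @return A list of class `rope_spec`.
#' @export
rope_spec <- function(interval = c(-0.1, 0.1), ci_level = 0.95,
                      max_rope_overlap = 0.10,
                      interval_type = c("eti", "hdi")) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            ci_level > 0, ci_level < 1)
  structure(list(interval = interval, ci_level = ci_level,
                 max_rope_overlap = max_rope_overlap,
                 interval_type = match.arg(interval_type)),
            class = "rope_spec")
}

#' Standardize a numeric feature
#'
#' Centers to mean 0 and scales to unit standard deviation (denominator
#' `n - 1`).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param name Feature name used in error messages.
#' @return List with `values` (standardized vector), `mean` and `sd`.
#' @export
standardize <- function(values, name = "feature") {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("missing values in ", name, call. = FALSE)
  mu <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant feature: ", name, call. = FALSE)
  }
  list(values = (values - mu) / s, mean = mu, sd = s)
}

#' Batch-normalize a predictor
#'
#' Removes additive batch effects by centering within each batch, then
#' scales by the pooled (post-centering) standard deviation. Adding a
#' constant to the raw predictor — globally or per batch — leaves the
#' output unchanged.
#'
#' @param values Numeric vector.
#' @param batch Batch labels (coerced to factor), same length.
#' @return Numeric vector, per-batch mean 0, pooled sd 1.
#' @export
batch_normalize <- function(values, batch) {
  stopifnot(length(values) == length(batch))
  batch <- as.factor(batch)
  centered <- values - stats::ave(values, batch)
  s <- stats::sd(centered)
  if (!is.finite(s) || s == 0) {
    stop("cannot batch-normalize: no residual variation", call. = FALSE)
  }
  centered / s
}

# internal: coerce labels to a 0/1 case indicator
.case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad) > 0) {
    stop("labels must be 'case'/'control' (got: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  as.integer(labels == "case")
}

# internal: run a JAGS model and return a posterior_draws object.
# `monitor` is a named list mapping JAGS variable names to output
# parameter names (vector variables expand by index).
.jags_sample <- function(model_string, data, monitor, mcmc) {
  n_adapt <- min(mcmc$warmup, 1000L)
  n_burn <- mcmc$warmup - n_adapt
  n_keep <- mcmc$iterations - mcmc$warmup
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(mcmc$seed) * 1009 + ch * 7907) %%
                                  2147483399) + 1L)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) stats::update(jm, n.iter = n_burn, progress.bar = "none")
  s <- rjags::jags.samples(jm, variable.names = names(monitor),
                           n.iter = n_keep, progress.bar = "none")
  mats <- list()
  for (v in names(monitor)) {
    arr <- s[[v]]  # dims: (var dim, iterations, chains)
    k <- dim(arr)[1]
    nm <- monitor[[v]]
    stopifnot(length(nm) == k)
    for (i in seq_len(k)) mats[[nm[i]]] <- arr[i, , ]
  }
  draws <- array(NA_real_, dim = c(n_keep, mcmc$chains, length(mats)),
                 dimnames = list(NULL, NULL, names(mats)))
  for (i in seq_along(mats)) draws[, , i] <- mats[[i]]
  posterior_draws(draws)
}

#' Fit the Bayesian linear group-difference model
#'
#' Models a (standardized) GAGome feature as Gaussian with the case
#' indicator as predictor, optionally adjusting for covariates
#' (experimental batch and sample age in months in the study's adjusted
#' models). All coefficients carry the `prior_spec()` t prior; the
#' residual scale has a half-t(3, 0, 2) prior.
#'
#' @param feature Numeric response vector (standardize upstream with
#'   [standardize()] to put the group coefficient on the standardized-mean
#'   scale).
#' @param labels Case/control labels (`"case"`/`"control"`, logical, or
#'   0/1).
#' @param covariates Optional data frame of adjustment covariates aligned
#'   with `feature` (factors are dummy-coded).
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_draws` object with parameters `(Intercept)`,
#'   `group`, one per covariate column, and `sigma`.
#' @export
fit_linear_group_model <- function(feature, labels, covariates = NULL,
                                   prior = prior_spec(),
                                   mcmc = mcmc_config()) {
  g <- .case_indicator(labels)
  stopifnot(length(feature) == length(g))
  if (anyNA(feature)) stop("missing values in feature", call. = FALSE)
  if (length(unique(g)) < 2) stop("both classes must be present", call. = FALSE)
  X <- matrix(g, ncol = 1, dimnames = list(NULL, "group"))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(feature))
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  # mean-center the design columns: leaves every coefficient unchanged
  # (only the intercept is reparameterized) and decorrelates it from the
  # intercept, which greatly improves MCMC mixing
  X <- scale(X, center = TRUE, scale = FALSE)
  tau <- 1 / prior$scale^2
  model <- sprintf("
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0 + inprod(X[i,], b), pow(sigma, -2))
  }
  b0 ~ dt(%g, %g, %g)
  for (j in 1:P) { b[j] ~ dt(%g, %g, %g) }
  sigma ~ dt(0, 0.25, 3) T(0,)
}", prior$location, tau, prior$df, prior$location, tau, prior$df)
  .jags_sample(model,
               data = list(y = feature, X = X, N = length(feature), P = ncol(X)),
               monitor = list(b0 = "(Intercept)", b = colnames(X),
                              sigma = "sigma"),
               mcmc = mcmc)
}

# internal: interval of the pooled draws per the rope_spec
.posterior_interval <- function(d, rope) {
  a <- (1 - rope$ci_level) / 2
  if (rope$interval_type == "eti") {
    c(.order_stat_quantile(d, a), .order_stat_quantile(d, 1 - a))
  } else {
    s <- sort(d)
    n <- length(s)
    k <- max(1L, ceiling(rope$ci_level * n))
    if (k >= n) return(c(s[1], s[n]))
    starts <- seq_len(n - k)
    widths <- s[starts + k] - s[starts]
    i <- which.min(widths)
    c(s[i], s[i + k])
  }
}

#' ROPE equivalence decision for a posterior parameter
#'
#' Computes the 95% posterior interval of the named parameter (equal-
#' tailed by default; endpoints are order statistics of the pooled
#' post-warmup draws), the fraction of in-interval draws falling inside
#' the ROPE, and the credibility verdict: credible iff the interval
#' excludes zero, the ROPE overlap is at most `max_rope_overlap`, and the
#' MCMC convergence gates pass.
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name (default `"group"`).
#' @param rope A [rope_spec()].
#' @param feature Optional feature name recorded in the decision.
#' @return A list of class `equivalence_decision` with fields `feature`,
#'   `mean`, `ci_low`, `ci_high`, `rope_overlap`, `rhat_max`, `ess_min`,
#'   `diagnostics_pass` and `credible`.
#' @export
rope_decision <- function(draws, parameter = "group", rope = rope_spec(),
                          feature = parameter) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% draws$parameters) {
    stop("parameter not found in draws: ", parameter, call. = FALSE)
  }
  d <- as.vector(draws$draws[, , parameter])
  ci <- .posterior_interval(d, rope)
  inside <- d >= ci[1] & d <= ci[2]
  overlap <- mean(d[inside] >= rope$interval[1] & d[inside] <= rope$interval[2])
  diag <- mcmc_diagnostics(draws)
  excludes_zero <- ci[1] > 0 || ci[2] < 0
  structure(list(
    feature = feature,
    mean = mean(d),
    ci_low = ci[1],
    ci_high = ci[2],
    rope_overlap = overlap,
    rhat_max = diag$rhat_max,
    ess_min = diag$ess_min,
    diagnostics_pass = diag$pass,
    credible = excludes_zero && overlap <= rope$max_rope_overlap && diag$pass
  ), class = "equivalence_decision")
}

#' @export
print.equivalence_decision <- function(x, ...) {
  cat(sprintf("%s: mean %.3f, 95%% CI [%.3f, %.3f], ROPE overlap %.1f%%, %s\n",
              x$feature, x$mean, x$ci_low, x$ci_high, 100 * x$rope_overlap,
              if (x$credible) "credible" else "not credible"))
  invisible(x)
}

#' Bayesian equivalence screen over GAGome features
#'
#' For each analysis feature: standardizes it, fits the linear
#' group-difference model (optionally covariate-adjusted), and renders
#' the ROPE equivalence decision. Per-feature MCMC seeds derive from
#' `mcmc$seed` so the screen is reproducible and features are sampled
#' independently.
#'
#' @param features Data frame / tibble of feature columns (samples in
#'   rows; no missing values in screened columns).
#' @param labels Case/control labels.
#' @param feature_names Columns of `features` to screen (default: all
#'   except `sample_id`).
#' @param covariates Optional adjustment covariate data frame.
#' @param prior,mcmc,rope Model settings.
#' @return Tibble with one row per feature: `feature`, `mean`, `ci_low`,
#'   `ci_high`, `rope_overlap`, `rhat_max`, `ess_min`, `credible`.
#' @export
equivalence_screen <- function(features, labels, feature_names = NULL,
                               covariates = NULL, prior = prior_spec(),
                               mcmc = mcmc_config(), rope = rope_spec()) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features), "sample_id")
  }
  rows <- lapply(seq_along(feature_names), function(i) {
    f <- feature_names[i]
    z <- standardize(features[[f]], name = f)
    mc <- mcmc
    mc$seed <- as.integer((as.numeric(mcmc$seed) * 131 + i) %% 2147483399)
    fit <- fit_linear_group_model(z$values, labels, covariates = covariates,
                                  prior = prior, mcmc = mc)
    dec <- rope_decision(fit, "group", rope, feature = f)
    tibble::tibble(feature = f, mean = dec$mean, ci_low = dec$ci_low,
                   ci_high = dec$ci_high, rope_overlap = dec$rope_overlap,
                   rhat_max = dec$rhat_max, ess_min = dec$ess_min,
                   credible = dec$credible)
  })
  do.call(rbind, rows)
}

#' Fit a Bayesian logistic scoring model
#'
#' Fits case/control status with a Bernoulli-logit likelihood on the given
#' predictors, each internally centered and scaled (constants recorded in
#' the model and reapplied at prediction). The t priors regularize the
#' coefficients, so separated data still yield finite estimates. The
#' model's score is the posterior-mean linear predictor, i.e. the log-odds
#' of lung cancer.
#'
#' @param X Data frame of numeric predictors (no missing values). Apply
#'   batch normalization ([batch_normalize()]) or transforms (e.g. log
#'   cfDNA concentration) upstream.
#' @param labels Case/control labels (both classes required).
#' @param prior,mcmc Model settings.
#' @return A list of class `score_model`: `predictors`, `center`, `scale`,
#'   `coef` (posterior means on the normalized scale, `(Intercept)`
#'   first), `draws` (`posterior_draws`), `diagnostics`.
#' @export
fit_logistic_score <- function(X, labels, prior = prior_spec(),
                               mcmc = mcmc_config()) {
  X <- as.data.frame(X, check.names = FALSE)
  stopifnot(ncol(X) >= 1, all(vapply(X, is.numeric, logical(1))))
  if (anyNA(X)) stop("missing predictor values", call. = FALSE)
  g <- .case_indicator(labels)
  stopifnot(nrow(X) == length(g))
  if (length(unique(g)) < 2) {
    stop("labels contain a single class; cannot fit score model", call. = FALSE)
  }
  center <- vapply(X, mean, numeric(1))
  scl <- vapply(X, stats::sd, numeric(1))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(as.matrix(X), 2, center), 2, scl, "/")
  tau <- 1 / prior$scale^2
  model <- sprintf("
model {
  for (i in 1:N) {
    y[i] ~ dbern(ilogit(b0 + inprod(X[i,], b)))
  }
  b0 ~ dt(%g, %g, %g)
  for (j in 1:P) { b[j] ~ dt(%g, %g, %g) }
}", prior$location, tau, prior$df, prior$location, tau, prior$df)
  draws <- .jags_sample(model,
                        data = list(y = g, X = Xs, N = nrow(Xs), P = ncol(Xs)),
                        monitor = list(b0 = "(Intercept)", b = colnames(X)),
                        mcmc = mcmc)
  coef <- vapply(draws$parameters,
                 function(p) mean(draws$draws[, , p]), numeric(1))
  structure(list(predictors = colnames(X), center = center, scale = scl,
                 coef = coef, draws = draws,
                 diagnostics = mcmc_diagnostics(draws)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("Bayesian logistic score model (log-odds of lung cancer)\n")
  cat("predictors:", paste(x$predictors, collapse = ", "), "\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' Predict log-odds scores
#'
#' Applies the model's stored normalization constants to the new
#' predictors and evaluates the posterior-mean linear predictor.
#'
#' @param model A `score_model`.
#' @param X Data frame containing the model's predictor columns.
#' @return Numeric vector of log-odds scores.
#' @export
predict_log_odds <- function(model, X) {
  stopifnot(inherits(model, "score_model"))
  X <- as.data.frame(X, check.names = FALSE)
  missing <- setdiff(model$predictors, names(X))
  if (length(missing) > 0) {
    stop("missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Xm <- as.matrix(X[, model$predictors, drop = FALSE])
  if (anyNA(Xm)) stop("missing predictor values", call. = FALSE)
  Xs <- sweep(sweep(Xm, 2, model$center), 2, model$scale, "/")
  as.vector(model$coef[1] + Xs %*% model$coef[-1])
}

#' Serialize / deserialize a score model
#'
#' Writes the predictor names, normalization constants, posterior-mean
#' coefficients and posterior summary statistics to JSON. The full draw
#' array is not serialized; a reloaded model predicts identically but
#' cannot be re-diagnosed.
#'
#' @param model A `score_model`.
#' @param path JSON path.
#' @return `write_score_model()`: `path`, invisibly. `read_score_model()`:
#'   a `score_model` (without draws).
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  obj <- list(
    predictors = model$predictors,
    center = as.list(model$center),
    scale = as.list(model$scale),
    coef = as.list(model$coef),
    posterior_summary = posterior_summary(model$draws)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(
    predictors = unlist(obj$predictors),
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    coef = unlist(obj$coef),
    draws = NULL,
    diagnostics = NULL
  ), class = "score_model")
}
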