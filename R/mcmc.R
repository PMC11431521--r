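# Posterior draw container and MCMC convergence diagnostics.
#
# R-hat is the split-chain potential scale reduction factor: each chain is
# halved, and sqrt(((n-1)/n * W + B/n) / W) is computed from the between-
# and within-half variances. ESS uses the multi-chain autocorrelation
# estimate rho_t = 1 - (W - mean_chain_acov_t) / var_plus with Geyer's
# initial monotone positive sequence truncation. Point-mass draws (zero
# variance everywhere) are treated as converged: R-hat 1, ESS = #draws.

#' Posterior draws with convergence diagnostics
#'
#' Container for post-warmup MCMC draws: an `iterations x chains x
#' parameters` array plus per-parameter split R-hat and effective sample
#' size, computed on construction.
#'
#' @param draws A numeric array `iterations x chains x parameters`
#'   (with parameter dimnames), or a matrix `iterations x chains` for a
#'   single parameter.
#' @param parameters Optional character vector of parameter names.
#' @return An object of class `posterior_draws` with elements `draws`,
#'   `parameters` and `diagnostics` (tibble: parameter, rhat, ess).
#' @export
posterior_draws <- function(draws, parameters = NULL) {
  if (is.matrix(draws)) draws <- array(draws, dim = c(dim(draws), 1L))
  stopifnot(is.array(draws), length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("at least 2 chains are required", call. = FALSE)
  if (is.null(parameters)) {
    parameters <- dimnames(draws)[[3]]
    if (is.null(parameters)) parameters <- paste0("par", seq_len(dim(draws)[3]))
  }
  stopifnot(length(parameters) == dim(draws)[3])
  dimnames(draws)[[3]] <- parameters
  diag <- tibble::tibble(
    parameter = parameters,
    rhat = vapply(parameters, function(p) split_rhat(draws[, , p]), numeric(1)),
    ess = vapply(parameters, function(p) ess_chains(draws[, , p]), numeric(1))
  )
  structure(list(draws = draws, parameters = parameters, diagnostics = diag),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("posterior_draws:", d[1], "iterations x", d[2], "chains x",
      d[3], "parameters\n")
  print(posterior_summary(x))
  invisible(x)
}

#' Summarize posterior draws
#'
#' @param x A `posterior_draws` object.
#' @return Tibble with per-parameter posterior mean, sd, 2.5/97.5%
#'   quantiles, R-hat and ESS.
#' @export
posterior_summary <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  pooled <- function(p) as.vector(x$draws[, , p])
  tibble::tibble(
    parameter = x$parameters,
    mean = vapply(x$parameters, function(p) mean(pooled(p)), numeric(1)),
    sd = vapply(x$parameters, function(p) stats::sd(pooled(p)), numeric(1)),
    q2.5 = vapply(x$parameters, function(p) .order_stat_quantile(pooled(p), 0.025), numeric(1)),
    q97.5 = vapply(x$parameters, function(p) .order_stat_quantile(pooled(p), 0.975), numeric(1)),
    rhat = x$diagnostics$rhat,
    ess = x$diagnostics$ess
  )
}

# equal-tailed quantile as an order statistic of the pooled draws
.order_stat_quantile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as between-chain disagreement.
#' Values below 1.01 indicate convergence. Chains that are all constant and
#' equal give 1; chains stuck at different constants give `Inf`.
#'
#' @param x Matrix of draws, `iterations x chains` (>= 2 chains).
#' @return The split R-hat scalar.
#' @export
split_rhat <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("at least 2 chains are required", call. = FALSE)
  n_half <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n_half), j], x[seq(nrow(x) - n_half + 1, nrow(x)), j])
  }))
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    if (B == 0) return(1)
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size across chains
#'
#' Multi-chain effective sample size of the pooled post-warmup draws,
#' using the combined autocorrelation estimate with Geyer initial monotone
#' positive-sequence truncation. Degenerate (zero-variance) draws return
#' the total number of draws.
#'
#' @param x Matrix of draws, `iterations x chains` (>= 2 chains).
#' @return Estimated effective sample size.
#' @export
ess_chains <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("at least 2 chains are required", call. = FALSE)
  n <- nrow(x); m <- ncol(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(n * m)
  max_lag <- n - 1
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0 (= ~1)
  # Geyer: sum of adjacent pairs, truncated at first non-positive pair,
  # then enforced monotone non-increasing
  max_pairs <- floor((length(rho) - 1) / 2)
  psum <- numeric(0)
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (p <= 0) break
    psum <- c(psum, p)
  }
  if (length(psum) > 1) psum <- cummin(psum)
  tau <- 1 + 2 * sum(psum)
  max(n * m / tau, 1)
}

#' MCMC convergence gate
#'
#' Applies the study's convergence criteria to a set of posterior draws:
#' every parameter must have split R-hat below 1.01 and effective sample
#' size above 1000.
#'
#' @param x A `posterior_draws` object.
#' @param rhat_max R-hat threshold (fail at or above it); default 1.01.
#' @param ess_min ESS threshold (fail at or below it); default 1000.
#' @return List with `pass` (logical), `rhat_max`, `ess_min` (worst
#'   observed values) and the per-parameter `diagnostics` tibble.
#' @export
mcmc_diagnostics <- function(x, rhat_max = 1.01, ess_min = 1000) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- x$diagnostics
  list(
    pass = all(d$rhat < rhat_max) && all(d$ess > ess_min),
    rhat_max = max(d$rhat),
    ess_min = min(d$ess),
    diagnostics = d
  )
}
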