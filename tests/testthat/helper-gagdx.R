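# Shared test helpers: reduced MCMC profiles sized so the convergence
# gates (R-hat < 1.01, ESS > 1000) still pass, plus brute-force oracles
# for AUC and threshold calibration.

# reduced sampling profile for simulation studies
mcmc_fast <- function(seed = 1L) {
  mcmc_config(chains = 2L, iterations = 2000L, warmup = 400L, seed = seed)
}

# slightly longer profile for single-fit comparisons
mcmc_mid <- function(seed = 1L) {
  mcmc_config(chains = 2L, iterations = 3000L, warmup = 500L, seed = seed)
}

# brute-force AUC: explicit Mann-Whitney pair count with ties at 1/2
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == "case" | labels == 1]
  ct <- scores[labels == "control" | labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# exhaustive threshold search over midpoints between sorted unique scores
# (plus the extremes), keeping the cut-off that maximizes sensitivity
# under the specificity floor; reports the achieved (sens, spec)
threshold_bruteforce <- function(scores, labels, min_spec) {
  g <- as.integer(labels == "case" | labels == 1)
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, (head(u, -1) + tail(u, -1)) / 2, u, max(u) + 1)
  best <- NULL
  for (t in sort(cand)) {
    spec <- mean(scores[g == 0] <= t)
    sens <- mean(scores[g == 1] > t)
    if (spec >= min_spec && (is.null(best) || sens > best["sens"] + 1e-12)) {
      best <- c(sens = sens, spec = spec)
    }
  }
  best
}

# complete random GAGome profile table
random_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    prof <- empty_profile(sprintf("r%02d", seq_len(n)))
    for (d in gag_panel()$name) prof[[d]] <- round(stats::runif(n, 0, 3), 3)
    prof
  })
}
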