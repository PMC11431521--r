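# Standardization, batch normalization, ROPE decisions, convergence
# diagnostics, and the linear / logistic model fits against classical
# oracles.

test_that("standardize centers and scales with the n-1 denominator", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1))
  expect_equal(z$mean, 2)
  expect_equal(z$sd, 1)
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  z2 <- standardize(x)
  expect_equal(z2$mean, 5)
  expect_equal(z2$sd, sqrt(32 / 7))
  expect_equal(z2$values[1], -1.4031, tolerance = 1e-4)
  expect_lt(abs(mean(standardize(rnorm(50))$values)), 1e-12)
  expect_error(standardize(rep(3, 10), name = "flat"), "flat")
})

test_that("batch normalization absorbs additive batch shifts", {
  withr::with_seed(8, {
    x <- rnorm(60)
    batch <- rep(c("B1", "B2"), 30)
  })
  z <- batch_normalize(x, batch)
  expect_equal(stats::sd(z), 1)
  expect_equal(as.numeric(tapply(z, batch, mean)), c(0, 0))
  # adding constants (global or per batch) changes nothing
  x2 <- x + 5 + 2 * (batch == "B2")
  expect_equal(batch_normalize(x2, batch), z)
})

test_that("split R-hat and ESS behave on iid, stuck and degenerate chains", {
  withr::with_seed(1, m <- matrix(rnorm(4000), 2000, 2))
  expect_lt(split_rhat(m), 1.01)
  expect_gt(ess_chains(m), 2000)
  pd <- posterior_draws(m, "theta")
  expect_true(mcmc_diagnostics(pd)$pass)

  # chains stuck at different constants: hand split-R-hat diverges
  stuck <- cbind(rep(0, 1000), rep(1, 1000))
  expect_identical(split_rhat(stuck), Inf)
  expect_false(mcmc_diagnostics(posterior_draws(stuck, "theta"))$pass)

  # within-chain drift is caught by the split
  drift <- cbind(seq(0, 3, length.out = 2000) + rnorm(2000, sd = 0.1),
                 seq(0, 3, length.out = 2000) + rnorm(2000, sd = 0.1))
  expect_gt(split_rhat(drift), 1.01)

  # point mass everywhere: treated as converged
  flat <- matrix(2, 500, 2)
  expect_equal(split_rhat(flat), 1)
  expect_equal(ess_chains(flat), 1000)

  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(posterior_draws(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("ESS agrees with coda on autocorrelated chains", {
  skip_if_not_installed("coda")
  withr::with_seed(4, {
    ar <- replicate(2, as.numeric(stats::arima.sim(list(ar = 0.7), 4000)))
  })
  mine <- ess_chains(ar)
  theirs <- sum(vapply(seq_len(ncol(ar)), function(j) {
    unname(coda::effectiveSize(coda::mcmc(ar[, j])))
  }, numeric(1)))
  expect_lt(abs(mine - theirs) / theirs, 0.25)
})

test_that("ROPE decisions follow the interval/overlap/diagnostics rule", {
  # point mass outside the ROPE: credible
  pm <- posterior_draws(matrix(0.5, 1000, 2), "group")
  d <- rope_decision(pm, "group")
  expect_equal(c(d$ci_low, d$ci_high), c(0.5, 0.5))
  expect_equal(d$rope_overlap, 0)
  expect_true(d$credible)

  # draws symmetric about zero: interval contains zero, not credible
  withr::with_seed(2, sym <- matrix(rnorm(8000, 0, 1), 4000, 2))
  expect_false(rope_decision(posterior_draws(sym, "group"))$credible)

  expect_error(rope_decision(pm, "nonexistent"), "not found")
})

test_that("ROPE overlap matches the conditional-normal oracle", {
  # draws ~ N(0.12, 0.05): 95% ETI ~ [0.022, 0.218]; the in-interval mass
  # below 0.1 is (Phi(-0.4) - 0.025) / 0.95 ~ 0.336 -> not credible
  withr::with_seed(7, m <- matrix(rnorm(80000, 0.12, 0.05), 20000, 4))
  d <- rope_decision(posterior_draws(m, "group"), "group")
  expect_equal(d$ci_low, 0.12 - 1.96 * 0.05, tolerance = 0.01)
  expect_equal(d$ci_high, 0.12 + 1.96 * 0.05, tolerance = 0.01)
  oracle <- (stats::pnorm(-0.4) - 0.025) / 0.95
  expect_equal(d$rope_overlap, oracle, tolerance = 0.03)
  expect_false(d$credible)
})

test_that("interval endpoints are order statistics, invariant to draw order", {
  withr::with_seed(11, m <- matrix(rnorm(6000), 3000, 2))
  d <- rope_decision(posterior_draws(m, "g"), "g")
  expect_true(d$ci_low %in% m)
  expect_true(d$ci_high %in% m)
  perm <- matrix(sample(as.vector(m)), 3000, 2)
  d2 <- rope_decision(posterior_draws(perm, "g"), "g")
  expect_equal(c(d2$ci_low, d2$ci_high), c(d$ci_low, d$ci_high))
})

test_that("the linear group model recovers the least-squares estimate", {
  withr::with_seed(31, {
    g <- rep(c("control", "case"), c(150, 250))
    y <- rnorm(400, 0.8 * (g == "case"))
  })
  fit <- fit_linear_group_model(y, g, mcmc = mcmc_mid(seed = 13))
  post_mean <- mean(fit$draws[, , "group"])
  ols <- unname(stats::coef(stats::lm(y ~ I(g == "case")))[2])
  expect_lt(abs(post_mean - ols), 0.05)
  expect_true(mcmc_diagnostics(fit)$pass)
  expect_setequal(fit$parameters, c("(Intercept)", "group", "sigma"))
})

test_that("covariate adjustment removes a batch confound", {
  withr::with_seed(32, {
    n <- 400
    g <- rep(c("control", "case"), each = n / 2)
    batch <- rbinom(n, 1, ifelse(g == "case", 0.8, 0.2))  # confounded
    y <- rnorm(n, 1.0 * batch)  # no true group effect
  })
  fit <- fit_linear_group_model(
    y, g, covariates = data.frame(batch = batch == 1),
    mcmc = mcmc_mid(seed = 21)
  )
  expect_lt(abs(mean(fit$draws[, , "group"])), 0.2)
  expect_equal(mean(fit$draws[, , "batchTRUE"] > 0), 1, tolerance = 0.01)
  expect_error(fit_linear_group_model(y, rep("case", n)), "both classes")
})

test_that("widening the prior scale barely moves a data-dominated posterior", {
  withr::with_seed(33, {
    g <- rep(c("control", "case"), c(28, 85))
    y <- rnorm(113, 1.0 * (g == "case"))
  })
  f1 <- fit_linear_group_model(y, g, prior = prior_spec(scale = 2),
                               mcmc = mcmc_mid(seed = 5))
  f2 <- fit_linear_group_model(y, g, prior = prior_spec(scale = 20),
                               mcmc = mcmc_mid(seed = 5))
  expect_lt(abs(mean(f1$draws[, , "group"]) - mean(f2$draws[, , "group"])),
            0.05)
})

test_that("the logistic score recovers a maximum-likelihood oracle", {
  withr::with_seed(41, {
    n <- 600
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    eta <- -0.5 + 1.2 * X$a - 0.8 * X$b
    lab <- ifelse(runif(n) < stats::plogis(eta), "case", "control")
  })
  m <- fit_logistic_score(X, lab, mcmc = mcmc_mid(seed = 3))
  gl <- stats::glm(I(lab == "case") ~ a + b, data = X, family = stats::binomial())
  # model coefficients are on the internally standardized predictor scale
  ml <- unname(stats::coef(gl))
  ml_std <- unname(c(ml[1] + sum(ml[2:3] * m$center), ml[2:3] * m$scale))
  expect_equal(unname(m$coef), ml_std, tolerance = 0.15)
  expect_true(m$diagnostics$pass)
})

test_that("t priors keep separated data finite", {
  X <- data.frame(x = c(-3, -2, -1, 1, 2, 3))
  lab <- c("control", "control", "control", "case", "case", "case")
  m <- fit_logistic_score(X, lab, mcmc = mcmc_fast(seed = 2))
  expect_true(all(is.finite(m$coef)))
  expect_lt(abs(m$coef[["x"]]), 15)
  expect_error(fit_logistic_score(X, rep("case", 6)), "single class")
})

test_that("log-odds prediction is the posterior-mean linear predictor", {
  m <- structure(list(
    predictors = c("p1", "p2"),
    center = c(p1 = 0, p2 = 0), scale = c(p1 = 1, p2 = 1),
    coef = c("(Intercept)" = 0.5, p1 = 2, p2 = -1),
    draws = NULL, diagnostics = NULL
  ), class = "score_model")
  X <- data.frame(p1 = c(1, 0, 2), p2 = c(1, 0, 1))
  expect_equal(predict_log_odds(m, X), c(1.5, 0.5, 3.5))
  # monotone in a positive-coefficient predictor
  X2 <- data.frame(p1 = seq(-2, 2, length.out = 9), p2 = 0)
  expect_true(all(diff(predict_log_odds(m, X2)) > 0))
  # zero model scores zero
  m0 <- m; m0$coef[] <- 0
  expect_equal(predict_log_odds(m0, X), c(0, 0, 0))
  expect_error(predict_log_odds(m, data.frame(p1 = 1)), "p2")
})

test_that("score models round-trip through JSON", {
  withr::with_seed(51, {
    X <- data.frame(u = rnorm(80), v = rnorm(80))
    lab <- ifelse(runif(80) < stats::plogis(X$u), "case", "control")
  })
  m <- fit_logistic_score(X, lab, mcmc = mcmc_fast(seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  expect_equal(predict_log_odds(m2, X), predict_log_odds(m, X))
})
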