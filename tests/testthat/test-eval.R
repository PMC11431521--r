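# ROC/AUC, threshold calibration, bootstrap, combined test, stratified
# sensitivity, correlations and cohort characteristic tests.

test_that("AUC equals the Mann-Whitney pair count", {
  ctrl <- c(0.1, 0.2, 0.3, 0.9)
  cases <- c(0.25, 0.8, 1.2, 1.5)
  scores <- c(ctrl, cases)
  labels <- rep(c("control", "case"), each = 4)
  expect_equal(roc_auc(scores, labels)$auc, 13 / 16)
  # perfectly separated and all-tied extremes
  expect_equal(roc_auc(c(0, 0, 1, 1), c("control", "control", "case", "case"))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), rep(c("control", "case"), 3))$auc, 0.5)
  expect_error(roc_auc(1:4, rep("case", 4)), "both classes")
})

test_that("AUC matches the brute-force oracle and is rank invariant", {
  withr::with_seed(10, {
    for (i in 1:40) {
      n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
      scores <- round(c(rnorm(n0), rnorm(n1, 0.5)), 1)  # rounding makes ties
      labels <- rep(c("control", "case"), c(n0, n1))
      expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels))
      # strictly increasing transform preserves AUC
      expect_equal(roc_auc(exp(scores) + 3, labels)$auc,
                   roc_auc(scores, labels)$auc)
    }
  })
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    scores <- c(rnorm(40), rnorm(60, 0.7))
    labels <- rep(c("control", "case"), c(40, 60))
  })
  theirs <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("control", "case"),
    direction = "<"))))
  expect_equal(roc_auc(scores, labels)$auc, theirs)
})

test_that("threshold calibration honors the specificity floor", {
  scores <- c(0.1, 0.2, 0.3, 0.9, 0.25, 0.8, 1.2, 1.5)
  labels <- rep(c("control", "case"), each = 4)
  expect_equal(threshold_at_specificity(scores, labels, 1.0), 0.9)
  s <- sensitivity_at_specificity(scores, labels, 1.0)
  expect_equal(s$sensitivity, 0.5)
  # one allowed false positive at 75%
  expect_equal(threshold_at_specificity(scores, labels, 0.75), 0.3)
  expect_equal(sensitivity_at_specificity(scores, labels, 0.75)$sensitivity, 0.75)
  # vacuous floor: everything above the smallest control is positive
  s0 <- sensitivity_at_specificity(scores, labels, 1e-9)
  expect_equal(s0$sensitivity, 1)
  # full separation at 100% specificity
  sep <- c(1, 2, 3, 10, 11, 12)
  lab2 <- rep(c("control", "case"), each = 3)
  expect_equal(sensitivity_at_specificity(sep, lab2, 1.0)$sensitivity, 1)
})

test_that("calibrated sensitivity matches exhaustive cut-off search", {
  withr::with_seed(20, {
    for (i in 1:40) {
      n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
      scores <- round(c(rnorm(n0), rnorm(n1, 0.8)), 1)
      labels <- rep(c("control", "case"), c(n0, n1))
      for (ms in c(0.8, 0.9, 0.95, 1.0)) {
        got <- sensitivity_at_specificity(scores, labels, ms)
        oracle <- threshold_bruteforce(scores, labels, ms)
        expect_equal(got$sensitivity, unname(oracle["sens"]))
        expect_gte(got$specificity, ms)
      }
    }
  })
})

test_that("sensitivity is non-increasing in the specificity floor", {
  withr::with_seed(21, {
    scores <- c(rnorm(30), rnorm(50, 1))
    labels <- rep(c("control", "case"), c(30, 50))
  })
  sens <- vapply(seq(0.05, 1, by = 0.05), function(ms) {
    sensitivity_at_specificity(scores, labels, ms)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("the stratified bootstrap is seeded and degenerate at B = 1", {
  withr::with_seed(30, {
    scores <- c(rnorm(28), rnorm(85, 1))
    labels <- rep(c("control", "case"), c(28, 85))
  })
  b1 <- bootstrap_metrics(scores, labels, 0.95, B = 200, seed = 7)
  b2 <- bootstrap_metrics(scores, labels, 0.95, B = 200, seed = 7)
  expect_identical(b1$metrics, b2$metrics)
  b3 <- bootstrap_metrics(scores, labels, 0.95, B = 200, seed = 8)
  expect_false(identical(b1$metrics$ci_low, b3$metrics$ci_low))
  single <- bootstrap_metrics(scores, labels, 0.95, B = 1, seed = 1)
  expect_equal(single$metrics$ci_low, single$metrics$ci_high)
  # every replicate keeps the stratum sizes, so both classes always present
  expect_true(all(is.finite(b1$replicates)))
})

test_that("bootstrap percentile CIs cover a known AUC", {
  withr::with_seed(31, {
    hits <- vapply(1:60, function(r) {
      # true AUC for N(0,1) vs N(d,1) is pnorm(d / sqrt(2)); d chosen for 0.8
      d <- sqrt(2) * stats::qnorm(0.8)
      scores <- c(rnorm(28), rnorm(85, d))
      labels <- rep(c("control", "case"), c(28, 85))
      b <- bootstrap_metrics(scores, labels, 0.95, B = 500, seed = r)
      b$metrics$ci_low[1] <= 0.8 && 0.8 <= b$metrics$ci_high[1]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.85)
})

test_that("the combined test applies the specificity budget and flags", {
  toy <- tibble::tibble(
    sample_id = sprintf("t%d", 1:8),
    label = rep(c("control", "case"), each = 4),
    cfdna_score = c(0.1, 0.2, 0.3, NA, 0.25, 5.0, NA, 0.1),
    cfdna_status = c("available", "available", "available", "insufficient",
                     "available", "available", "missing", "insufficient"),
    gagome_score = c(1, 2, 3, 2.5, 9, 0.5, 8, 0.2)
  )
  dec <- combined_test(toy)
  cuts <- attr(dec, "cutoffs")
  expect_equal(unname(cuts["cfdna"]), 0.3)   # max available control score
  expect_equal(unname(cuts["gagome"]), 3)    # 95% floor on 4 controls -> max
  # case t5: cfDNA negative (0.25 <= 0.3) but GAGome positive -> reclassified
  expect_equal(dec$combined_call[5], "positive")
  expect_true(dec$reclassified_positive[5])
  # case t6: cfDNA positive alone
  expect_equal(dec$cfdna_call[6], "positive")
  expect_false(dec$reclassified_positive[6])
  # case t7 (missing cfDNA) counts as cfDNA negative; GAGome rescues it
  expect_equal(dec$cfdna_call[7], "negative")
  expect_equal(dec$combined_call[7], "positive")
  # case t8: insufficient cfDNA and GAGome negative -> combined negative
  expect_equal(dec$combined_call[8], "negative")
  # all controls negative here
  expect_true(all(dec$combined_call[1:4] == "negative"))
  expect_error(combined_test(toy[toy$label == "case", ]), "no controls")
})

test_that("combined positives decompose into cfDNA positives + reclassified", {
  withr::with_seed(40, {
    for (i in 1:20) {
      n <- 60
      status <- sample(c("available", "insufficient", "missing"), n, TRUE,
                       prob = c(0.7, 0.1, 0.2))
      toy <- tibble::tibble(
        sample_id = as.character(1:n),
        label = sample(rep(c("case", "control"), c(40, 20))),
        cfdna_score = ifelse(status == "available", rnorm(n, 1), NA),
        cfdna_status = status,
        gagome_score = rnorm(n)
      )
      if (!any(status == "available" & toy$label == "control")) next
      dec <- combined_test(toy)
      expect_equal(sum(dec$combined_call == "positive"),
                   sum(dec$cfdna_call == "positive") +
                     sum(dec$reclassified_positive))
      # specificity budget: floors 1.00 and 0.95 on the calibration controls
      ctrl <- dec$label == "control"
      spec <- mean(dec$combined_call[ctrl] == "negative")
      expect_gte(spec, 0.95 - 1e-12)
    }
  })
})

test_that("stage-stratified sensitivity pools II and III", {
  dec <- tibble::tibble(
    sample_id = as.character(1:21),
    label = c(rep("case", 19), "control", "control"),
    combined_call = c(rep("positive", 5), rep("negative", 4),    # stage I: 5/9
                      rep("positive", 4), rep("negative", 6),    # II-III: 4/10
                      rep("negative", 2))
  )
  stages <- c(rep("I", 9), rep("II", 5), rep("III", 5), NA, NA)
  tab <- stage_stratified_sensitivity(dec, stages)
  expect_equal(tab$sensitivity[tab$stratum == "I"], 5 / 9)
  expect_equal(round(100 * tab$sensitivity[tab$stratum == "I"], 1), 55.6)
  expect_equal(tab$sensitivity[tab$stratum == "II-III"], 0.4)
  expect_false(tab$defined[tab$stratum == "IV"])
  expect_true(is.na(tab$sensitivity[tab$stratum == "IV"]))
  # all positive -> all strata 100%
  dec$combined_call <- c(rep("positive", 19), "negative", "negative")
  tab2 <- stage_stratified_sensitivity(dec, stages)
  expect_equal(tab2$sensitivity[tab2$defined], c(1, 1))
})

test_that("rank correlations detect identity and independence", {
  withr::with_seed(50, {
    f <- tibble::tibble(feat = rexp(1000))
    c1 <- tibble::tibble(same = f$feat, mono = f$feat^3 + 2,
                         indep = rnorm(1000))
  })
  tab <- feature_cfdna_correlation(f, c1)
  expect_equal(tab$rho[tab$measure == "same"], 1)
  expect_equal(tab$rho[tab$measure == "mono"], 1)  # rank invariance
  expect_lt(abs(tab$rho[tab$measure == "indep"]), 0.1)
  short <- tibble::tibble(feat = c(1, 2, NA, NA))
  expect_error(feature_cfdna_correlation(short, tibble::tibble(m = c(1, NA, 2, 3))),
               "fewer than 3")
})

test_that("cohort characteristic tests use Pearson chi-square and t-tests", {
  counts <- study_cohort_counts()
  smoking <- counts$smoking[rownames(counts$smoking) != "missing", ]
  res <- chisq_from_table(smoking)
  expect_equal(res$statistic, 6.13, tolerance = 0.01)
  expect_equal(res$df, 2L)
  expect_equal(round(res$p_value, 3), 0.047)
  # df = 2 closed form: p = exp(-chi2 / 2)
  expect_equal(res$p_value, exp(-res$statistic / 2), tolerance = 1e-12)
  withr::with_seed(60, {
    for (i in 1:20) {
      tab <- matrix(rpois(6, 20) + 1, nrow = 3)
      r <- chisq_from_table(tab)
      expect_equal(r$p_value, exp(-r$statistic / 2), tolerance = 1e-12)
    }
  })
  # identical group proportions -> statistic 0, p 1
  eq <- matrix(c(10, 20, 30, 1, 2, 3), nrow = 3)
  req <- chisq_from_table(eq)
  expect_equal(req$statistic, 0)
  expect_equal(req$p_value, 1)
  expect_error(chisq_from_table(matrix(c(0, 0, 5, 5), 2)), "zero")
})

test_that("cohort_characteristics runs both test families per variable", {
  co <- simulate_cohort(default_sim_params(seed = 77))
  res <- cohort_characteristics(co$samples)
  expect_setequal(res$variable, c("age_years", "sex", "smoking"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  res_s <- cohort_characteristics(co$samples, t_variant = "student")
  age_w <- res$df[res$variable == "age_years"]
  age_s <- res_s$df[res_s$variable == "age_years"]
  expect_equal(age_s, 111)        # pooled df = n - 2
  expect_false(isTRUE(all.equal(age_w, age_s)))
  expect_error(cohort_characteristics(co$samples[co$samples$group == "case", ]),
               "both classes")
})
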