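test_that("confusion metrics reproduce hand-computed proportions", {
  m <- confusion_metrics(17, 5, 12, 46)
  est <- setNames(m$estimate, m$metric)
  expect_equal(unname(est["accuracy"]), 63 / 80)
  expect_equal(unname(est["sensitivity"]), 17 / 29)
  expect_equal(unname(est["specificity"]), 46 / 51)
  expect_equal(unname(est["ppv"]), 17 / 22)
  expect_equal(unname(est["npv"]), 46 / 58)
  expect_true(all(m$estimate >= m$conf.low & m$estimate <= m$conf.high))

  m2 <- confusion_metrics(13, 4, 16, 47)
  est2 <- setNames(m2$estimate, m2$metric)
  expect_equal(round(unname(est2["sensitivity"]), 3), 0.448)
  expect_equal(round(unname(est2["specificity"]), 3), 0.922)
  expect_equal(round(unname(est2["ppv"]), 3), 0.765)
})

test_that("zero-denominator metrics are flagged undefined, not reported as 0", {
  m <- confusion_metrics(0, 0, 0, 10)
  est <- setNames(m$estimate, m$metric)
  expect_equal(unname(est["accuracy"]), 1)
  expect_equal(unname(est["specificity"]), 1)
  expect_true(is.na(est["sensitivity"]))
  expect_true(m$undefined[m$metric == "sensitivity"])
  expect_true(m$undefined[m$metric == "ppv"])
  expect_error(confusion_metrics(0, 0, 0, 0), class = "abpm_validation_error")
})

test_that("accuracy is the prevalence-weighted combination of sens and spec", {
  for (s in 1:25) {
    cc <- withr::with_seed(s, rpois(4, 12) + 1)
    m <- confusion_metrics(cc[1], cc[2], cc[3], cc[4])
    est <- setNames(m$estimate, m$metric)
    prev <- (cc[1] + cc[3]) / sum(cc)
    expect_equal(unname(est["accuracy"]),
                 prev * est[["sensitivity"]] + (1 - prev) * est[["specificity"]])
  }
})

test_that("exact binomial intervals hit the boundaries and match a root-finding oracle", {
  expect_equal(proportion_ci(0, 10)$conf.low, 0)
  expect_equal(proportion_ci(10, 10)$conf.high, 1)
  ci <- proportion_ci(63, 80)
  oracle <- cp_ci_oracle(63, 80)
  expect_equal(ci$conf.low, oracle[1], tolerance = 1e-9)
  expect_equal(ci$conf.high, oracle[2], tolerance = 1e-9)
  for (k in c(1, 5, 40, 79)) {
    o <- cp_ci_oracle(k, 80)
    ci <- proportion_ci(k, 80)
    expect_equal(c(ci$conf.low, ci$conf.high), o, tolerance = 1e-9)
  }
  expect_error(proportion_ci(5, 0), class = "abpm_validation_error")
  expect_error(proportion_ci(-1, 10), class = "abpm_validation_error")
})

test_that("Wilson intervals are available and narrower than exact at midrange", {
  cp <- proportion_ci(40, 80)
  wi <- proportion_ci(40, 80, method = "wilson")
  expect_lt(wi$conf.high - wi$conf.low, cp$conf.high - cp$conf.low)
})

test_that("separable scores give AUC 1 and all-tied scores give AUC 0.5", {
  r1 <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                     c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r1$auc, 1)
  r2 <- roc_analysis(rep(5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(r2$auc, 0.5)
})

test_that("trapezoid AUC equals brute-force pairwise concordance on random instances", {
  for (s in 1:100) {
    withr::with_seed(s, {
      n <- sample(10:40, 1)
      labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
      scores <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01 * (s %% 2))
      a <- roc_analysis(scores, labels)$auc
      expect_equal(a, auc_oracle(scores, labels), tolerance = 1e-12)
    })
  }
})

test_that("AUC matches the reference ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    labels <- c(rep(TRUE, 25), rep(FALSE, 35))
    scores <- rnorm(60, ifelse(labels, 1, 0))
  })
  a <- roc_analysis(scores, labels)
  ref <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(a$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("Youden ties break toward the more sensitive cut-point", {
  r <- roc_analysis(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  # J = 0.5 at thresholds 2 and 4; the lower one is more sensitive
  expect_equal(r$youden_cutoff, 2)
  expect_equal(r$youden_value, 0.5)
  expect_equal(r$youden_sensitivity, 1)
})

test_that("direction = lower mirrors the analysis of a protective marker", {
  withr::with_seed(7, {
    labels <- rep(c(TRUE, FALSE), each = 20)
    scores <- rnorm(40, ifelse(labels, -1, 1))
  })
  lo <- roc_analysis(scores, labels, direction = "lower")
  hi <- roc_analysis(-scores, labels, direction = "higher")
  expect_equal(lo$auc, hi$auc)
  expect_equal(lo$youden_cutoff, -hi$youden_cutoff)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), class = "abpm_validation_error")
})

test_that("odds ratios reproduce the cross-product on published-style counts", {
  or1 <- odds_ratio_2x2(17, 12, 5, 46)
  expect_equal(or1$odds_ratio, (17 * 46) / (12 * 5))
  expect_lt(or1$conf.low, or1$odds_ratio)
  or2 <- odds_ratio_2x2(20, 9, 25, 26)
  expect_equal(or2$odds_ratio, (20 * 26) / (9 * 25))
  expect_equal(odds_ratio_2x2(7, 7, 7, 7)$odds_ratio, 1)
})

test_that("odds ratio is invariant to transposing the 2x2 table", {
  for (s in 1:20) {
    cc <- withr::with_seed(s, rpois(4, 10) + 1)
    a <- odds_ratio_2x2(cc[1], cc[2], cc[3], cc[4])
    b <- odds_ratio_2x2(cc[1], cc[3], cc[2], cc[4])   # transpose
    expect_equal(a$odds_ratio, b$odds_ratio)
    expect_equal(a$p.value, b$p.value)
  }
})

test_that("zero cells use the continuity correction; empty margins abort", {
  or <- odds_ratio_2x2(10, 0, 3, 12)
  expect_true(or$corrected)
  expect_true(is.finite(or$odds_ratio))
  expect_error(odds_ratio_2x2(0, 0, 5, 5), class = "abpm_validation_error")
})

test_that("logistic regression on one binary predictor equals the cross-product OR", {
  # expand (a, b, c, d) = (17, 12, 5, 46) into patient-level data
  df <- tibble::tibble(
    y = rep(c(TRUE, TRUE, FALSE, FALSE), c(17, 12, 5, 46)),
    x = rep(c(TRUE, FALSE, TRUE, FALSE), c(17, 12, 5, 46)))
  fit <- logistic_fit(df, "y", "x")
  expect_equal(fit$odds_ratio, (17 * 46) / (12 * 5), tolerance = 1e-6)
  expect_false(fit$separation)
  # and the Wald interval matches the Woolf interval on the same table
  or <- odds_ratio_2x2(17, 12, 5, 46)
  expect_equal(fit$conf.low, or$conf.low, tolerance = 1e-4)
  expect_equal(fit$conf.high, or$conf.high, tolerance = 1e-4)
})

test_that("null-predictor confidence intervals cover 1 in most replicates", {
  hits <- 0
  for (s in 1:200) {
    df <- withr::with_seed(1000 + s, tibble::tibble(
      y = runif(50) < 0.4, x = runif(50) < 0.5))
    ok <- tryCatch({
      f <- logistic_fit(df, "y", "x")
      f$conf.low <= 1 && f$conf.high >= 1
    }, error = function(e) NA)
    if (isTRUE(ok)) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("perfect separation is detected and flagged", {
  df <- tibble::tibble(y = rep(c(TRUE, FALSE), each = 15),
                       x = rep(c(TRUE, FALSE), each = 15))
  fit <- logistic_fit(df, "y", "x")
  expect_true(fit$separation)
  expect_error(logistic_fit(tibble::tibble(y = c(TRUE, FALSE), x = c(1, 1)),
                            "y", "x"),
               class = "abpm_validation_error")   # constant predictor
})

test_that("adjusted fits report the predictor term with the adjusted flag", {
  df <- withr::with_seed(17, tibble::tibble(
    age = rnorm(80, 64, 10),
    x = runif(80) < 0.4,
    y = runif(80) < plogis(-1 + 1.2 * (runif(80) < 0.4))))
  fit <- logistic_fit(df, "y", "x", covariates = "age")
  expect_true(all(fit$adjusted))
  expect_true("x" %in% fit$term)
})

test_that("group comparison picks the conventional test", {
  g <- rep(c("a", "b"), each = 10)
  same <- rep(1:10, 2)
  res <- group_compare(same, g, "continuous", normal = "no")
  expect_equal(res$method, "mann-whitney")
  expect_equal(res$p.value, 1)

  # reverse-dipping 2x2 from the clinical comparison: clearly significant
  vals <- rep(c(TRUE, FALSE, TRUE, FALSE), c(17, 12, 5, 46))
  grp <- rep(c("AF+", "AF-"), c(29, 51))
  res2 <- group_compare(vals, grp, "categorical")
  expect_equal(res2$method, "chi-square")
  expect_lt(res2$p.value, 0.01)

  expect_error(group_compare(1:5, rep("a", 5), "continuous"),
               class = "abpm_validation_error")
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  # table (1, 8; 9, 1): an expected cell below 5 forces the exact test
  vals <- rep(c(TRUE, FALSE, TRUE, FALSE), c(1, 8, 9, 1))
  grp <- rep(c("g1", "g2"), c(9, 10))
  res <- group_compare(vals, grp, "categorical")
  expect_equal(res$method, "fisher")
  # enumeration oracle: sum of probabilities of tables as or less probable
  m <- 10; n_ <- 9; k <- 10                 # TRUE margin, by column margins
  probs <- dhyper(0:10, m, n_, k)
  obs <- dhyper(9, m, n_, k)                # 9 TRUE in group g2... via margins
  p_oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(res$p.value, p_oracle, tolerance = 1e-10)
})

test_that("display rounding follows the half-away-from-zero convention", {
  expect_equal(as_percent(0.7875), 79)
  expect_equal(as_percent(0.745), 75)      # 74.5 rounds up, not to even
  expect_equal(as_percent(0.5862069), 59)
  expect_equal(round_half_away(12.5), 13)
  expect_equal(round_half_away(-12.5), -13)
  fm <- format_diag_percent(confusion_metrics(17, 5, 12, 46))
  expect_equal(fm$pct[fm$metric == "accuracy"], 79)
})
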