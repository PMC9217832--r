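#' Exact and approximate confidence intervals for a binomial proportion
#'
#' Default is the Clopper--Pearson exact interval (beta-quantile form); the
#' Wilson score interval is available by flag. Vectorized over `k`, `n`.
#'
#' @param k number of successes (0..n).
#' @param n number of trials (> 0).
#' @param conf_level confidence level, default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return tibble with columns `conf.low`, `conf.high`.
#' @export
proportion_ci <- function(k, n, conf_level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(n <= 0) || any(k < 0) || any(k > n) || any(k != round(k))) {
    abort("need integer 0 <= k <= n, n > 0", class = "abpm_validation_error")
  }
  a <- 1 - conf_level
  if (method == "clopper-pearson") {
    lo <- ifelse(k == 0, 0, qbeta(a / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, qbeta(1 - a / 2, k + 1, n - k))
  } else {
    z <- qnorm(1 - a / 2)
    p <- k / n
    den <- 1 + z^2 / n
    mid <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- pmax(0, mid - half); hi <- pmin(1, mid + half)
  }
  tibble::tibble(conf.low = lo, conf.high = hi)
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Computes accuracy, sensitivity, specificity, and positive/negative
#' predictive values with binomial confidence intervals from the four
#' confusion counts (test vs reference standard). A metric with a zero
#' denominator is returned as `NA` and flagged `undefined`, never silently 0.
#'
#' @param tp,fp,fn,tn confusion counts (true/false positives/negatives
#'   against the reference diagnosis).
#' @param conf_level confidence level for the intervals.
#' @param ci_method passed to [proportion_ci()].
#' @return an `abpm_diag` tibble: `metric`, `estimate` (proportion),
#'   `conf.low`, `conf.high`, `numerator`, `denominator`, `undefined`; the
#'   counts are kept in attribute `counts`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn, conf_level = 0.95,
                              ci_method = "clopper-pearson") {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "abpm_validation_error")
  }
  n <- sum(counts)
  if (n == 0) abort("empty confusion table", class = "abpm_validation_error")
  num <- c(accuracy = tp + tn, sensitivity = tp, specificity = tn,
           ppv = tp, npv = tn)
  den <- c(accuracy = n, sensitivity = tp + fn, specificity = tn + fp,
           ppv = tp + fp, npv = tn + fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- tibble::tibble(conf.low = rep(NA_real_, 5), conf.high = NA_real_)
  ok <- den > 0
  if (any(ok)) ci[ok, ] <- proportion_ci(num[ok], den[ok], conf_level, ci_method)
  out <- tibble::tibble(metric = names(num), estimate = unname(est),
                        conf.low = ci$conf.low, conf.high = ci$conf.high,
                        numerator = unname(num), denominator = unname(den),
                        undefined = !ok)
  attr(out, "counts") <- counts
  class(out) <- c("abpm_diag", class(out))
  out
}

#' Build confusion counts from test and reference vectors
#'
#' @param test logical vector of test results.
#' @param reference logical vector of reference-standard diagnoses.
#' @return named counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(test, reference) {
  stopifnot(length(test) == length(reference),
            is.logical(test), is.logical(reference))
  c(tp = sum(test & reference), fp = sum(test & !reference),
    fn = sum(!test & reference), tn = sum(!test & !reference))
}

#' Empirical ROC analysis with Youden-index cut-point
#'
#' Builds the empirical ROC curve of a continuous marker against a binary
#' reference over every distinct observed value (prediction positive when the
#' marker is at or beyond the threshold in the positive direction), computes
#' the area under the curve by the trapezoidal rule -- which equals the
#' tie-corrected two-sample rank (Mann--Whitney) concordance -- with a
#' Hanley--McNeil confidence interval, and selects the threshold maximizing
#' the Youden index J = sensitivity + specificity - 1, breaking ties toward
#' the more sensitive threshold.
#'
#' @param scores numeric marker values.
#' @param labels logical reference diagnoses (both classes required).
#' @param direction `"higher"` (default) if larger values indicate disease,
#'   `"lower"` otherwise.
#' @param conf_level confidence level for the AUC interval.
#' @return an `abpm_roc` object: `curve` tibble (`threshold`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden`), `auc`, `auc_ci`, `youden_cutoff`,
#'   `youden_value`, `direction`, class counts.
#' @export
roc_analysis <- function(scores, labels, direction = c("higher", "lower"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels), is.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort("both classes required for ROC analysis",
          class = "abpm_validation_error")
  }
  s <- if (direction == "higher") scores else -scores
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!labels] < t), numeric(1))
  acc <- (sens * n1 + spec * n0) / (n1 + n0)

  # trapezoid over the full curve including the (0,0) and (1,1) endpoints
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((tpr[-length(tpr)] + tpr[-1]) / 2 * (fpr[-length(fpr)] - fpr[-1]))

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  auc_ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]   # lowest internal threshold = most sensitive
  to_orig <- function(t) if (direction == "higher") t else -t
  curve <- tibble::tibble(threshold = to_orig(thr), sensitivity = sens,
                          specificity = spec, accuracy = acc, youden = j)
  structure(list(curve = curve, auc = auc, auc_se = se, auc_ci = auc_ci,
                 youden_cutoff = to_orig(thr[best]), youden_value = j[best],
                 youden_sensitivity = sens[best], youden_specificity = spec[best],
                 youden_accuracy = acc[best],
                 direction = direction, n_pos = n1, n_neg = n0,
                 conf_level = conf_level),
            class = "abpm_roc")
}

#' @export
print.abpm_roc <- function(x, ...) {
  cat(sprintf("<abpm_roc> AUC %.3f (%.0f%% CI %.3f-%.3f), n+=%d n-=%d\n",
              x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  cat(sprintf("  Youden cut-point %.4g (J=%.3f, sens %.3f, spec %.3f)\n",
              x$youden_cutoff, x$youden_value, x$youden_sensitivity,
              x$youden_specificity))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x an `abpm_roc` object.
#' @param ... unused.
#' @export
tidy.abpm_roc <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @export
glance.abpm_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc.conf.low = x$auc_ci[1],
                 auc.conf.high = x$auc_ci[2], youden_cutoff = x$youden_cutoff,
                 youden = x$youden_value, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Odds ratio of a 2x2 exposure table
#'
#' Cross-product odds ratio with the Woolf log-scale confidence interval and
#' a two-sided Wald p-value. A zero cell triggers the Haldane--Anscombe 0.5
#' continuity correction of all four cells, flagged in the output.
#'
#' @param a exposed cases, `b` unexposed cases, `c` exposed controls, `d`
#'   unexposed controls.
#' @param b,c,d see `a`.
#' @param conf_level confidence level.
#' @return tibble: `odds_ratio`, `conf.low`, `conf.high`, `p.value`,
#'   `corrected` (Haldane--Anscombe flag).
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("negative cell", class = "abpm_validation_error")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("empty margin in 2x2 table", class = "abpm_validation_error")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(log(or) - z * se); hi <- exp(log(or) + z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  tibble::tibble(odds_ratio = unname(or), conf.low = unname(lo),
                 conf.high = unname(hi), p.value = unname(p),
                 corrected = corrected)
}

#' Logistic regression odds ratios (univariate or covariate-adjusted)
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor,
#' optionally adjusted for confounders, via iteratively reweighted least
#' squares (`stats::glm`). Reports per-term odds ratios with Wald confidence
#' intervals and p-values. Quasi-complete separation (fitted probabilities
#' numerically 0/1, diverging coefficient) is detected and flagged rather
#' than silently reported.
#'
#' @param data data frame containing outcome and predictors.
#' @param outcome name of the logical/0-1 outcome column.
#' @param predictor name of the predictor of interest.
#' @param covariates optional character vector of adjustment covariates.
#' @param conf_level confidence level.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return tibble: `term`, `odds_ratio`, `conf.low`, `conf.high`, `p.value`,
#'   `adjusted`, `separation`, `converged`.
#' @export
logistic_fit <- function(data, outcome, predictor, covariates = NULL,
                         conf_level = 0.95, max_iter = 100, tol = 1e-10) {
  vars <- c(predictor, covariates)
  df <- as.data.frame(data)[, c(outcome, vars), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  for (v in vars) {
    x <- df[[v]]
    if (is.logical(x)) df[[v]] <- as.integer(x)
    if (is.numeric(df[[v]]) && sd(df[[v]]) == 0) {
      abort(paste0("constant predictor: ", v), class = "abpm_validation_error")
    }
  }
  if (nrow(df) <= length(vars) + 1) {
    abort("more terms than observations", class = "abpm_validation_error")
  }
  df[[outcome]] <- y
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                  paste0("`", vars, "`", collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = df,
        control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge in %d iterations", max_iter),
          class = "abpm_convergence_error")
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(abs(est[-1]) > 15)) separation <- TRUE  # diverging log-odds
  z <- qnorm(1 - (1 - conf_level) / 2)
  terms <- names(est)[-1]
  idx <- match(terms, names(est))
  tibble::tibble(term = gsub("`", "", terms),
                 odds_ratio = exp(unname(est[idx])),
                 conf.low = exp(unname(est[idx] - z * se[idx])),
                 conf.high = exp(unname(est[idx] + z * se[idx])),
                 p.value = unname(2 * pnorm(-abs(est[idx] / se[idx]))),
                 adjusted = !is.null(covariates),
                 separation = separation,
                 converged = fit$converged)
}

#' Two-group comparison with conventional test selection
#'
#' Continuous variables: Student's t-test when both groups pass a
#' Shapiro--Wilk normality check (or `normal = "yes"`), otherwise the
#' Mann--Whitney test. Categorical variables: chi-square test, switching to
#' Fisher's exact test when any expected cell count is below 5. Delegates to
#' the standard `stats` routines.
#'
#' @param values vector of observations (numeric, or logical/factor for
#'   categorical).
#' @param group two-level grouping vector.
#' @param type `"continuous"` or `"categorical"`.
#' @param normal `"auto"` (Shapiro--Wilk at 0.05), `"yes"`, or `"no"`.
#' @return tibble: `p.value`, `method`.
#' @export
group_compare <- function(values, group,
                          type = c("continuous", "categorical"),
                          normal = c("auto", "yes", "no")) {
  type <- match.arg(type); normal <- match.arg(normal)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("need exactly two non-empty groups", class = "abpm_validation_error")
  }
  split_vals <- split(values, droplevels(group))
  if (any(vapply(split_vals, length, integer(1)) == 0)) {
    abort("empty group", class = "abpm_validation_error")
  }
  if (type == "continuous") {
    use_t <- switch(normal,
      yes = TRUE, no = FALSE,
      auto = all(vapply(split_vals, function(v) {
        if (length(unique(v)) < 3 || length(v) < 3) return(FALSE)
        shapiro.test(v)$p.value > 0.05
      }, logical(1))))
    if (use_t) {
      tt <- t.test(split_vals[[1]], split_vals[[2]])
      tibble::tibble(p.value = tt$p.value, method = "t-test")
    } else {
      wt <- suppressWarnings(wilcox.test(split_vals[[1]], split_vals[[2]],
                                         exact = FALSE))
      tibble::tibble(p.value = wt$p.value, method = "mann-whitney")
    }
  } else {
    tab <- table(values, group)
    exp_counts <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
    if (any(exp_counts < 5)) {
      tibble::tibble(p.value = fisher.test(tab)$p.value, method = "fisher")
    } else {
      tibble::tibble(p.value = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                     method = "chi-square")
    }
  }
}

#' Display rounding for report tables
#'
#' Percentages rounded half away from zero to integer percent; odds ratios to
#' two significant figures (the convention of the printed clinical tables).
#'
#' @param x an `abpm_diag` tibble from [confusion_metrics()].
#' @return tibble with `pct`, `pct.conf.low`, `pct.conf.high` columns added.
#' @export
format_diag_percent <- function(x) {
  stopifnot(inherits(x, "abpm_diag"))
  dplyr::mutate(tibble::as_tibble(x),
                pct = as_percent(.data$estimate),
                pct.conf.low = as_percent(.data$conf.low),
                pct.conf.high = as_percent(.data$conf.high))
}
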