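#' Fit a two-class linear discriminant classifier
#'
#' First-principles Gaussian linear discriminant: with class means `m1`
#' (disease) and `m0` and pooled within-class covariance `S`, the weight
#' vector is `w = S^{-1} (m1 - m0)` and a case is called positive when
#' `w . x > cut-off`, where
#' `cut-off = w . (m1 + m0)/2 - log(prior1/prior0)`.
#' This is the Bayes rule under equal-covariance Gaussians and maximizes the
#' between-to-within variance ratio of the projection. `S` is the pooled
#' maximum-likelihood covariance (within-class scatter divided by n), so the
#' fit is exactly invariant under duplication of the whole sample. When the pooled
#' covariance is numerically singular (condition number above 1e10, e.g.
#' because derived features are linear combinations of others), a ridge term
#' `lambda * trace(S)/p` with `lambda = 1e-6` is added if `regularize = TRUE`,
#' otherwise the fit aborts naming the collinear columns.
#'
#' @param data data frame/tibble holding the outcome and feature columns.
#'   Logical features enter as 0/1; no standardization is applied
#'   (predictions are affine-invariant).
#' @param outcome name of the logical outcome column (TRUE = disease).
#' @param features character vector of feature column names; default
#'   [feature_columns()] intersected with `data`.
#' @param priors `"empirical"` (class frequencies, default) or `"equal"`.
#' @param regularize allow the ridge fallback for singular pooled covariance.
#' @return an `abpm_lda` object: `coefficients`, `cutoff`, `class_means`,
#'   `pooled_covariance`, `priors`, `column_order`, `lambda`, `n`.
#' @export
fit_lda <- function(data, outcome = "af_label", features = NULL,
                    priors = c("empirical", "equal"), regularize = TRUE) {
  priors <- match.arg(priors)
  data <- as.data.frame(data)
  if (is.null(features)) {
    features <- intersect(feature_columns(), names(data))
    if (length(features) == 0) {
      features <- setdiff(names(data)[vapply(data, function(c)
        is.numeric(c) || is.logical(c), logical(1))], outcome)
    }
  }
  stopifnot(all(features %in% names(data)), outcome %in% names(data))
  y <- data[[outcome]]
  if (!is.logical(y)) y <- as.logical(y)
  X <- as.matrix(as.data.frame(lapply(data[features], as.numeric)))
  if (anyNA(X) || anyNA(y)) {
    abort("missing cells in the feature matrix or outcome",
          class = "abpm_validation_error")
  }
  n1 <- sum(y); n0 <- sum(!y); n <- n1 + n0; p <- length(features)
  if (n1 < 2 || n0 < 2) {
    abort("each class needs at least 2 members", class = "abpm_validation_error")
  }
  if (p >= n) warn(sprintf("p = %d features >= n = %d samples", p, n))

  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  # maximum-likelihood pooled covariance (within-class scatter over n):
  # invariant under duplication of the whole sample
  S1 <- stats::cov(X[y, , drop = FALSE])
  S0 <- stats::cov(X[!y, , drop = FALSE])
  S <- ((n1 - 1) * S1 + (n0 - 1) * S0) / n

  lambda <- 0
  sv <- tryCatch(svd(S, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > 1e10) {
    if (!regularize) {
      qrS <- qr(S)
      collinear <- features[qrS$pivot[seq(qrS$rank + 1, length.out = p - qrS$rank)]]
      abort(paste0("pooled covariance singular; collinear column(s): ",
                   paste(collinear, collapse = ", ")),
            class = "abpm_singular_error")
    }
    lambda <- 1e-6
    S <- S + lambda * max(sum(diag(S)) / p, 1e-8) * diag(p)
  }

  pr <- if (priors == "empirical") c(n0, n1) / n else c(0.5, 0.5)
  w <- drop(solve(S, m1 - m0))
  cutoff <- sum(w * (m1 + m0) / 2) - log(pr[2] / pr[1])
  structure(list(coefficients = setNames(w, features),
                 cutoff = cutoff,
                 class_means = list(neg = m0, pos = m1),
                 pooled_covariance = S,
                 priors = setNames(pr, c("neg", "pos")),
                 prior_spec = priors,
                 column_order = features,
                 lambda = lambda, n = n, n_pos = n1, n_neg = n0),
            class = "abpm_lda")
}

#' @export
print.abpm_lda <- function(x, ...) {
  cat(sprintf("<abpm_lda> %d features, n=%d (%d pos / %d neg), priors %s%s\n",
              length(x$coefficients), x$n, x$n_pos, x$n_neg, x$prior_spec,
              if (x$lambda > 0) sprintf(", ridge lambda=%g", x$lambda) else ""))
  cat(sprintf("  score > %.6g  ->  positive\n", x$cutoff))
  invisible(x)
}

#' Score and classify with a fitted discriminant
#'
#' @param object an `abpm_lda` model.
#' @param newdata data frame with the model's feature columns (logicals are
#'   coerced to 0/1), or a numeric matrix in `column_order`.
#' @param ... unused.
#' @return tibble: `score` (discriminant value) and `af_pred` (logical;
#'   positive strictly above the cut-off).
#' @export
predict.abpm_lda <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    X <- newdata
    if (ncol(X) != length(object$column_order)) {
      abort(sprintf("feature dimension mismatch: %d vs %d", ncol(X),
                    length(object$column_order)),
            class = "abpm_validation_error")
    }
  } else {
    newdata <- as.data.frame(newdata)
    missing_cols <- setdiff(object$column_order, names(newdata))
    if (length(missing_cols)) {
      abort(paste0("newdata lacks feature column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "abpm_validation_error")
    }
    X <- as.matrix(as.data.frame(lapply(newdata[object$column_order], as.numeric)))
  }
  score <- drop(X %*% object$coefficients)
  tibble::tibble(score = score, af_pred = score > object$cutoff)
}

#' @rdname fit_lda
#' @param x an `abpm_lda` object.
#' @param ... unused.
#' @export
tidy.abpm_lda <- function(x, ...) {
  tibble::tibble(term = x$column_order,
                 estimate = unname(x$coefficients),
                 mean_pos = unname(x$class_means$pos),
                 mean_neg = unname(x$class_means$neg))
}

#' @rdname fit_lda
#' @export
glance.abpm_lda <- function(x, ...) {
  tibble::tibble(n = x$n, n_pos = x$n_pos, n_neg = x$n_neg,
                 p = length(x$coefficients), cutoff = x$cutoff,
                 prior_pos = unname(x$priors["pos"]),
                 prior_neg = unname(x$priors["neg"]),
                 lambda = x$lambda)
}

#' Evaluate a discriminant model on a labelled cohort
#'
#' Resubstitution scores the supplied model on its own training table
#' (apparent accuracy); leave-one-out and k-fold cross-validation refit the
#' model per fold with the same settings (honest accuracy). A cross-validation
#' training fold missing a class is merged with the next fold with a warning.
#' Metrics come from [confusion_metrics()].
#'
#' @param data labelled feature table (outcome + feature columns).
#' @param model a fitted `abpm_lda` (required for resubstitution; refit per
#'   fold otherwise, using its feature list and prior specification).
#' @param scheme `"resubstitution"`, `"loocv"`, or `"kfold"`.
#' @param outcome outcome column name.
#' @param k folds for `"kfold"`.
#' @param seed RNG seed for the k-fold shuffle (required for `"kfold"`).
#' @param ... passed to [fit_lda()] on refits.
#' @return an `abpm_eval` object: `scheme`, `counts`, `metrics`
#'   ([confusion_metrics()] tibble), `predictions` tibble.
#' @export
evaluate_lda <- function(data, model = NULL,
                         scheme = c("resubstitution", "loocv", "kfold"),
                         outcome = "af_label", k = 5, seed = NULL, ...) {
  scheme <- match.arg(scheme)
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (!is.logical(y)) y <- as.logical(y)
  features <- if (!is.null(model)) model$column_order else NULL
  priors <- if (!is.null(model)) model$prior_spec else "empirical"

  if (scheme == "resubstitution") {
    if (is.null(model)) model <- fit_lda(data, outcome = outcome, ...)
    pred <- predict(model, data)$af_pred
  } else {
    n <- nrow(data)
    fold_id <- if (scheme == "loocv") seq_len(n) else {
      if (is.null(seed)) abort("k-fold evaluation needs a seed",
                               class = "abpm_validation_error")
      withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    }
    folds <- split(seq_len(n), fold_id)
    # a training fold must keep both classes; merge offending folds forward
    i <- 1
    while (i <= length(folds)) {
      train <- setdiff(seq_len(n), folds[[i]])
      if (length(unique(y[train])) < 2) {
        if (length(folds) == 1) {
          abort("cannot form folds with both classes",
                class = "abpm_validation_error")
        }
        warn("fold without both training classes; merged with next fold")
        j <- if (i < length(folds)) i + 1 else i - 1
        folds[[j]] <- sort(c(folds[[j]], folds[[i]]))
        folds[[i]] <- NULL
      } else i <- i + 1
    }
    pred <- rep(NA, n)
    for (f in folds) {
      fit <- fit_lda(data[setdiff(seq_len(n), f), , drop = FALSE],
                     outcome = outcome, features = features,
                     priors = priors, ...)
      pred[f] <- predict(fit, data[f, , drop = FALSE])$af_pred
    }
    pred <- as.logical(pred)
  }
  cc <- confusion_counts(pred, y)
  structure(list(scheme = scheme,
                 counts = cc,
                 metrics = confusion_metrics(cc["tp"], cc["fp"], cc["fn"], cc["tn"]),
                 predictions = tibble::tibble(truth = y, predicted = pred)),
            class = "abpm_eval")
}

#' @export
print.abpm_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<abpm_eval> %s: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$scheme,
              100 * m$estimate[m$metric == "accuracy"],
              100 * m$estimate[m$metric == "sensitivity"],
              100 * m$estimate[m$metric == "specificity"]))
  invisible(x)
}

#' @rdname evaluate_lda
#' @param x an `abpm_eval` object.
#' @export
tidy.abpm_eval <- function(x, ...) tibble::as_tibble(x$metrics)

#' @rdname evaluate_lda
#' @export
glance.abpm_eval <- function(x, ...) {
  m <- x$metrics
  g <- setNames(as.list(m$estimate), m$metric)
  tibble::as_tibble(c(list(scheme = x$scheme), g, as.list(x$counts)))
}

#' Serialize a fitted discriminant to structured text
#'
#' JSON with 17 significant digits, so the round-trip through
#' [read_lda()] reproduces the model to printed precision.
#'
#' @param model an `abpm_lda`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_lda <- function(model, path) {
  stopifnot(inherits(model, "abpm_lda"))
  obj <- list(column_order = model$column_order,
              coefficients = unname(model$coefficients),
              cutoff = model$cutoff,
              class_mean_neg = unname(model$class_means$neg),
              class_mean_pos = unname(model$class_means$pos),
              pooled_covariance = model$pooled_covariance,
              priors = unname(model$priors),
              prior_spec = model$prior_spec,
              lambda = model$lambda,
              n = model$n, n_pos = model$n_pos, n_neg = model$n_neg)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a discriminant model written by [write_lda()]
#'
#' @param path JSON path.
#' @return an `abpm_lda` object.
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$column_order
  S <- matrix(unlist(obj$pooled_covariance), nrow = length(feats),
              dimnames = list(feats, feats))
  structure(list(coefficients = setNames(obj$coefficients, feats),
                 cutoff = obj$cutoff,
                 class_means = list(neg = setNames(obj$class_mean_neg, feats),
                                    pos = setNames(obj$class_mean_pos, feats)),
                 pooled_covariance = S,
                 priors = setNames(obj$priors, c("neg", "pos")),
                 prior_spec = obj$prior_spec,
                 column_order = feats,
                 lambda = obj$lambda, n = obj$n,
                 n_pos = obj$n_pos, n_neg = obj$n_neg),
            class = "abpm_lda")
}
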