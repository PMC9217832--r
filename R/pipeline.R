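#' Single-parameter diagnostic accuracy table
#'
#' Mirrors the per-parameter evaluation of the clinical report: each binary
#' parameter is crossed with the reference label in a 2x2 table
#' ([confusion_metrics()]); each continuous parameter goes through
#' [roc_analysis()] with the metrics taken at the Youden-optimal cut-point.
#' The direction of a continuous marker is oriented so the positive class
#' has the higher mean.
#'
#' @param features labelled feature table (outcome + feature columns).
#' @param outcome outcome column name.
#' @param params parameter columns to evaluate; defaults to the binary flags,
#'   episode count, weighted variability and night-time pressures, the
#'   markers of clinical interest.
#' @return tibble: `parameter`, `type`, `direction`, `cutoff`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv` (proportions).
#' @export
single_parameter_accuracy <- function(features, outcome = "af_label",
                                      params = NULL) {
  df <- as.data.frame(features)
  y <- df[[outcome]]
  if (!is.logical(y)) y <- as.logical(y)
  if (is.null(params)) params <- intersect(feature_columns(), names(df))
  rows <- purrr::map(params, function(p) {
    x <- df[[p]]
    if (is.logical(x)) {
      cc <- confusion_counts(x, y)
      m <- confusion_metrics(cc["tp"], cc["fp"], cc["fn"], cc["tn"])
      est <- setNames(m$estimate, m$metric)
      tibble::tibble(parameter = p, type = "binary", direction = NA_character_,
                     cutoff = NA_real_, auc = NA_real_,
                     accuracy = est["accuracy"], sensitivity = est["sensitivity"],
                     specificity = est["specificity"], ppv = est["ppv"],
                     npv = est["npv"])
    } else {
      dir <- if (mean(x[y]) >= mean(x[!y])) "higher" else "lower"
      roc <- roc_analysis(x, y, direction = dir)
      pos <- if (dir == "higher") x >= roc$youden_cutoff else x <= roc$youden_cutoff
      cc <- confusion_counts(pos, y)
      m <- confusion_metrics(cc["tp"], cc["fp"], cc["fn"], cc["tn"])
      est <- setNames(m$estimate, m$metric)
      tibble::tibble(parameter = p, type = "continuous", direction = dir,
                     cutoff = roc$youden_cutoff, auc = roc$auc,
                     accuracy = est["accuracy"], sensitivity = est["sensitivity"],
                     specificity = est["specificity"], ppv = est["ppv"],
                     npv = est["npv"])
    }
  })
  dplyr::bind_rows(rows)
}

#' Univariate and covariate-adjusted odds-ratio table
#'
#' For each parameter, a univariate logistic fit against the outcome and a
#' multivariate fit adjusted for age, sex, disease duration and levodopa
#' equivalent daily dose (the study's confounders), reported as odds ratios
#' with Wald intervals.
#'
#' @param data labelled table holding parameters, outcome, and the
#'   adjustment covariates.
#' @param params parameter columns.
#' @param outcome outcome column.
#' @param covariates adjustment covariate columns present in `data`.
#' @return tibble: `parameter`, `analysis` (`univariate`/`multivariate`),
#'   `odds_ratio`, `conf.low`, `conf.high`, `p.value`, `separation`.
#' @export
odds_ratio_table <- function(data, params, outcome = "af_label",
                             covariates = c("age", "sex", "disease_duration",
                                            "ledd")) {
  df <- as.data.frame(data)
  if ("sex" %in% covariates && is.character(df$sex)) {
    df$sex <- as.integer(df$sex == "F")
  }
  covariates <- intersect(covariates, names(df))
  constant <- vapply(covariates, function(v)
    is.numeric(df[[v]]) && sd(df[[v]], na.rm = TRUE) == 0, logical(1))
  if (any(constant)) {
    inform(paste0("dropping constant adjustment covariate(s): ",
                  paste(covariates[constant], collapse = ", ")))
    covariates <- covariates[!constant]
  }
  rows <- purrr::map(params, function(p) {
    uni <- logistic_fit(df, outcome, p)
    uni <- uni[uni$term == p, ]
    multi <- logistic_fit(df, outcome, p, covariates = covariates)
    multi <- multi[multi$term == p, ]
    dplyr::bind_rows(
      tibble::tibble(parameter = p, analysis = "univariate",
                     odds_ratio = uni$odds_ratio, conf.low = uni$conf.low,
                     conf.high = uni$conf.high, p.value = uni$p.value,
                     separation = uni$separation),
      tibble::tibble(parameter = p, analysis = "multivariate",
                     odds_ratio = multi$odds_ratio, conf.low = multi$conf.low,
                     conf.high = multi$conf.high, p.value = multi$p.value,
                     separation = multi$separation))
  })
  dplyr::bind_rows(rows)
}

run_manifest <- function(dir, seed, config, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "abpmaf",
       version = as.character(utils::packageVersion("abpmaf")),
       seed = seed,
       config = config,
       input_md5 = sums)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic cohort directory
#'
#' Generates a cohort under [generate_cohort()] and writes it in the
#' canonical cohort-directory layout together with a run manifest (config
#' snapshot and seed), so identical manifests imply identical trees.
#'
#' @param config an [cohort_config()].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  write_manifest(run_manifest(dir, config$seed, unclass(config)),
                 file.path(dir, "manifest.json"))
  inform(sprintf("simulated %d patients into %s", config$n_patients, dir))
  invisible(dir)
}

#' Extract the labelled feature table from a cohort directory
#'
#' Reads the cohort ([read_cohort()]), extracts the parameter set per patient
#' ([extract_features()]), resolves the reference label (recorded
#' `af_label`, else [af_diagnosis()] on the autonomic subscores), and writes
#' `features.csv` (flags as 0/1) plus a manifest. Patients failing
#' validation or extraction are reported and skipped; it is an error if none
#' survive.
#'
#' @param cohort_dir directory of recording CSVs.
#' @param covariates_path covariates CSV (defaults to
#'   `cohort_dir/covariates.csv`).
#' @param out_dir output directory.
#' @param config a [feature_config()].
#' @param io a [io_config()].
#' @return the labelled feature tibble, invisibly.
#' @export
run_extract <- function(cohort_dir,
                        covariates_path = file.path(cohort_dir, "covariates.csv"),
                        out_dir, config = feature_config(), io = io_config()) {
  cov <- read_covariates(covariates_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(cov$patient_id, function(id) {
    tryCatch({
      rec <- read_recording(file.path(cohort_dir, paste0(id, ".csv")), io)
      extract_features(rec, config)
    }, error = function(e) {
      inform(sprintf("skipping patient %s: %s", id, conditionMessage(e)))
      NULL
    })
  })
  feats <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(feats) == 0) {
    abort("no patient passed validation and extraction",
          class = "abpm_validation_error")
  }
  lab <- cov[, c("patient_id", "age", "sex", "disease_duration", "ledd",
                 "cardiovagal_score", "adrenergic_score", "af_label")]
  need_derive <- is.na(lab$af_label)
  lab$af_label[need_derive] <- af_diagnosis(
    lab$cardiovagal_score[need_derive], lab$adrenergic_score[need_derive])
  out <- dplyr::inner_join(lab, feats, by = "patient_id")
  write_feature_table(out, file.path(out_dir, "features.csv"))
  write_manifest(run_manifest(out_dir, NA, unclass(config),
                              inputs = covariates_path),
                 file.path(out_dir, "extract_manifest.json"))
  inform(sprintf("extracted features for %d of %d patients", nrow(out), nrow(cov)))
  invisible(out)
}

#' Fit and evaluate the discriminant pipeline
#'
#' Fits the linear discriminant on the labelled feature table, evaluates it
#' by resubstitution (apparent performance, matching how a single reported
#' accuracy without a cross-validation statement is obtained) and by
#' leave-one-out cross-validation (honest performance), computes the
#' single-parameter accuracy table and the odds-ratio table, and writes
#' `model.json`, `lda_metrics.csv`, `single_parameters.csv`,
#' `odds_ratios.csv`, `accuracy_ranking.csv` and a manifest. Deterministic
#' given the seed.
#'
#' @param features labelled feature tibble (or path to a `features.csv`).
#' @param out_dir output directory.
#' @param priors prior specification for [fit_lda()].
#' @param seed seed recorded in the manifest (used only by k-fold schemes).
#' @param outcome outcome column.
#' @return list with `model`, `resubstitution`, `loocv`, `single`,
#'   `odds_ratios`, `ranking`, invisibly.
#' @export
run_fit_eval <- function(features, out_dir, priors = "empirical", seed = 1,
                         outcome = "af_label") {
  if (is.character(features)) features <- read_feature_table(features)
  y <- features[[outcome]]
  if (length(unique(y)) < 2) {
    abort("cohort has a single outcome class; cannot fit",
          class = "abpm_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- fit_lda(features, outcome = outcome, priors = priors)
  resub <- evaluate_lda(features, model, scheme = "resubstitution",
                        outcome = outcome)
  loocv <- evaluate_lda(features, model, scheme = "loocv", outcome = outcome)
  single <- single_parameter_accuracy(features, outcome = outcome)
  cat_params <- intersect(c("hypo_aw", "reverse_dipping", "pph"),
                          names(features))
  wbpv_bin <- "w_bpv" %in% names(features)
  or_data <- features
  if (wbpv_bin) {
    or_data$wbpv_increased <- or_data$w_bpv > feature_config()$wbpv_thr
    cat_params <- c(cat_params, "wbpv_increased")
  }
  ors <- odds_ratio_table(or_data, cat_params, outcome = outcome)

  ranking <- dplyr::arrange(
    dplyr::bind_rows(
      tibble::tibble(parameter = "LDA (all parameters)",
                     accuracy = resub$metrics$estimate[
                       resub$metrics$metric == "accuracy"]),
      single[, c("parameter", "accuracy")]),
    dplyr::desc(.data$accuracy))

  write_lda(model, file.path(out_dir, "model.json"))
  lda_tab <- dplyr::bind_rows(
    dplyr::mutate(format_diag_percent(resub$metrics), scheme = "resubstitution"),
    dplyr::mutate(format_diag_percent(loocv$metrics), scheme = "loocv"))
  write.csv(as.data.frame(lda_tab), file.path(out_dir, "lda_metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(single), file.path(out_dir, "single_parameters.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(ors), file.path(out_dir, "odds_ratios.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(ranking), file.path(out_dir, "accuracy_ranking.csv"),
            row.names = FALSE)
  write_manifest(run_manifest(out_dir, seed, list(priors = priors)),
                 file.path(out_dir, "fit_eval_manifest.json"))
  inform(sprintf("LDA resubstitution accuracy %.1f%%, LOOCV %.1f%%",
                 100 * resub$metrics$estimate[resub$metrics$metric == "accuracy"],
                 100 * loocv$metrics$estimate[loocv$metrics$metric == "accuracy"]))
  invisible(list(model = model, resubstitution = resub, loocv = loocv,
                 single = single, odds_ratios = ors, ranking = ranking))
}
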