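#' Orthostatic hypotension from head-up tilt measurements
#'
#' Applies the consensus criterion: a sustained fall of systolic pressure of
#' at least 20 mmHg or diastolic of at least 10 mmHg within 3 minutes of tilt.
#' Over the discrete cuff schedule (1, 3, 5 min) "sustained" means the drop
#' criterion holds at every measurement from its first occurrence through the
#' 3-minute mark; measurements after 3 min never change the result.
#'
#' @param baseline list or one-row data frame with `sbp`, `dbp` (supine
#'   baseline after at least 5 min rest).
#' @param standing data frame with `minutes_from_tilt`, `sbp`, `dbp`.
#' @return logical.
#' @export
detect_oh <- function(baseline, standing) {
  b <- as.list(baseline)
  stopifnot(!is.null(b$sbp), !is.null(b$dbp))
  standing <- as.data.frame(standing)
  within3 <- standing[standing$minutes_from_tilt <= 3, , drop = FALSE]
  if (nrow(within3) == 0) {
    abort("no standing measurement within 3 minutes of tilt",
          class = "abpm_validation_error")
  }
  within3 <- within3[order(within3$minutes_from_tilt), , drop = FALSE]
  met <- (b$sbp - within3$sbp >= 20) | (b$dbp - within3$dbp >= 10)
  if (!any(met)) return(FALSE)
  all(met[min(which(met)):length(met)])
}

#' Supine hypertension
#'
#' TRUE when any supine measurement (after at least 5 minutes of rest) shows
#' systolic pressure of 140 mmHg or more, or diastolic of 90 mmHg or more.
#'
#' @param supine data frame with `sbp`, `dbp`.
#' @return logical.
#' @export
detect_sh <- function(supine) {
  supine <- as.data.frame(supine)
  if (nrow(supine) == 0) abort("no supine measurements", class = "abpm_validation_error")
  any(supine$sbp >= 140 | supine$dbp >= 90)
}

#' Autonomic-failure diagnosis from composite autonomic subscores
#'
#' The reference-standard rule: autonomic failure is present when the
#' cardiovagal plus adrenergic subscores of the (sudomotor-free) composite
#' autonomic score sum to 2 or more. Subscore derivation from the reflex
#' tests is outside this package; the subscores are inputs.
#'
#' @param cardiovagal_score,adrenergic_score non-negative integer vectors.
#' @return logical vector.
#' @export
af_diagnosis <- function(cardiovagal_score, adrenergic_score) {
  stopifnot(length(cardiovagal_score) == length(adrenergic_score))
  ok <- function(s) all(!is.na(s)) && all(s >= 0) && all(s == round(s))
  if (!ok(cardiovagal_score) || !ok(adrenergic_score)) {
    abort("subscores must be non-negative integers",
          class = "abpm_validation_error")
  }
  (cardiovagal_score + adrenergic_score) >= 2
}

#' Read a tilt-test measurement table
#'
#' Canonical header: `patient_id,phase,minutes_from_tilt,sbp,dbp` with phase
#' `supine_baseline` or `standing`.
#'
#' @param path tilt CSV path.
#' @return tibble.
#' @export
read_tilt <- function(path) {
  x <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  need <- c("patient_id", "phase", "minutes_from_tilt", "sbp", "dbp")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s: tilt table needs columns %s", path,
                  paste(need, collapse = ",")), class = "abpm_format_error")
  }
  stopifnot(all(x$phase %in% c("supine_baseline", "standing")))
  x
}
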