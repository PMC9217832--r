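#' I/O configuration for ABPM recordings
#'
#' @param min_valid_fraction minimum fraction of expected measurement slots
#'   that must carry a valid reading for a recording to be accepted. The
#'   expected slot count is derived from the recording span and `cadence_min`.
#' @param cadence_min programmed measurement interval in minutes.
#' @param require_awakening require at least one diary awakening event
#'   (disable only when the fixed clock-time day/night fallback will be used
#'   downstream).
#' @return an `abpm_io_config` list.
#' @export
io_config <- function(min_valid_fraction = 0.70, cadence_min = 15,
                      require_awakening = TRUE) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1, cadence_min > 0)
  structure(list(min_valid_fraction = min_valid_fraction,
                 cadence_min = cadence_min,
                 require_awakening = require_awakening),
            class = "abpm_io_config")
}

.DIARY_KINDS <- c("sleep_onset", "awakening", "meal")

#' Construct an ABPM recording
#'
#' Bundles one patient's timestamped cuff readings with the behavioural diary
#' (sleep onset, awakening, meals) recorded alongside. Readings are sorted by
#' time; all downstream feature extraction consumes this container.
#'
#' @param patient_id opaque patient identifier.
#' @param readings data frame with columns `timestamp` (POSIXct), `sbp`,
#'   `dbp`, and optionally `mbp`, `hr`. A missing/`NA` mean arterial pressure
#'   is derived as `dbp + (sbp - dbp)/3` and flagged in column `mbp_derived`.
#' @param diary data frame with columns `timestamp` (POSIXct) and `kind`
#'   (one of `"sleep_onset"`, `"awakening"`, `"meal"`); may have zero rows.
#' @param config an [io_config()].
#' @param validate run the recording-level invariant checks.
#' @return an `abpm_recording` object.
#' @export
abpm_recording <- function(patient_id, readings, diary = NULL,
                           config = io_config(), validate = TRUE) {
  stopifnot(is.character(patient_id), length(patient_id) == 1, nzchar(patient_id))
  readings <- tibble::as_tibble(readings)
  if (!all(c("timestamp", "sbp", "dbp") %in% names(readings))) {
    abort("readings must have columns timestamp, sbp, dbp",
          class = "abpm_format_error")
  }
  if (nrow(readings) == 0) {
    abort("recording has no readings", class = "abpm_validation_error")
  }
  if (!"mbp" %in% names(readings)) readings$mbp <- NA_real_
  if (!"hr" %in% names(readings)) readings$hr <- NA_real_
  readings$mbp_derived <- is.na(readings$mbp)
  readings$mbp <- ifelse(is.na(readings$mbp),
                         readings$dbp + (readings$sbp - readings$dbp) / 3,
                         readings$mbp)
  readings <- dplyr::arrange(readings, .data$timestamp)
  readings <- readings[, c("timestamp", "sbp", "dbp", "mbp", "hr", "mbp_derived")]

  if (is.null(diary) || nrow(as.data.frame(diary)) == 0) {
    diary <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                            kind = character())
  } else {
    diary <- tibble::as_tibble(diary)
    stopifnot(all(c("timestamp", "kind") %in% names(diary)))
    bad <- setdiff(unique(diary$kind), .DIARY_KINDS)
    if (length(bad)) {
      abort(paste0("unknown diary event kind: ", paste(bad, collapse = ", ")),
            class = "abpm_format_error")
    }
    diary <- dplyr::arrange(diary, .data$timestamp)
  }

  rec <- structure(list(patient_id = patient_id, readings = readings,
                        diary = diary),
                   class = "abpm_recording")
  if (validate) validate_recording(rec, config)
  rec
}

#' Validate an ABPM recording against its invariants
#'
#' Checks per-reading plausibility bounds (`sbp > dbp > 0`, 40--300 / 20--200
#' mmHg, `dbp <= mbp <= sbp`), strictly increasing timestamps, a total span of
#' 20--30 h, diary coherence, and recording completeness against the expected
#' slot count.
#'
#' @inheritParams abpm_recording
#' @param x an `abpm_recording`.
#' @return `x`, invisibly; aborts with class `abpm_validation_error` otherwise.
#' @export
validate_recording <- function(x, config = io_config()) {
  stopifnot(inherits(x, "abpm_recording"))
  r <- x$readings
  bad <- which(!(r$sbp > r$dbp & r$dbp > 0 &
                   r$sbp >= 40 & r$sbp <= 300 &
                   r$dbp >= 20 & r$dbp <= 200 &
                   r$mbp >= r$dbp & r$mbp <= r$sbp))
  if (length(bad)) {
    abort(sprintf(
      "patient %s: reading %d (%s) violates blood-pressure invariants (sbp=%s, dbp=%s, mbp=%s)",
      x$patient_id, bad[1], format_timestamp(r$timestamp[bad[1]]),
      r$sbp[bad[1]], r$dbp[bad[1]], signif(r$mbp[bad[1]], 4)),
      class = "abpm_validation_error")
  }
  if (nrow(r) > 1 && any(diff(as.numeric(r$timestamp)) <= 0)) {
    abort(sprintf("patient %s: duplicate reading timestamps", x$patient_id),
          class = "abpm_validation_error")
  }
  span_h <- hours_between(r$timestamp[1], r$timestamp[nrow(r)])
  if (span_h < 20 || span_h > 30) {
    abort(sprintf("patient %s: recording span %.2f h outside 20--30 h",
                  x$patient_id, span_h), class = "abpm_validation_error")
  }
  if (config$require_awakening && !any(x$diary$kind == "awakening")) {
    abort(sprintf("patient %s: diary has no awakening event", x$patient_id),
          class = "abpm_validation_error")
  }
  expected <- floor(span_h * 60 / config$cadence_min) + 1
  if (nrow(r) / expected < config$min_valid_fraction) {
    abort(sprintf(
      "patient %s: only %d of %d expected readings (min fraction %.2f)",
      x$patient_id, nrow(r), expected, config$min_valid_fraction),
      class = "abpm_validation_error")
  }
  invisible(x)
}

#' @export
print.abpm_recording <- function(x, ...) {
  r <- x$readings
  cat(sprintf("<abpm_recording> patient %s: %d readings, %s -- %s, %d diary events\n",
              x$patient_id, nrow(r), format_timestamp(r$timestamp[1]),
              format_timestamp(r$timestamp[nrow(r)]), nrow(x$diary)))
  invisible(x)
}

#' Read an ABPM recording from the canonical CSV pair
#'
#' Reads `<id>.csv` (header `timestamp,sbp,dbp,mbp,hr`; empty cell = missing
#' optional value) and, when present, the sibling diary file `<id>.diary.csv`
#' (header `timestamp,kind`). The patient id is the file stem. Rows with an
#' unparseable timestamp or missing mandatory pressures are counted, reported
#' via a warning, and dropped; rows that parse but violate the reading
#' invariants abort with the offending row identified.
#'
#' @param path path to the recording CSV.
#' @param config an [io_config()].
#' @return a validated `abpm_recording`; attribute `n_malformed` carries the
#'   count of dropped malformed rows.
#' @export
read_recording <- function(path, config = io_config()) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "abpm_io_error")
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("timestamp", "sbp", "dbp")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: missing mandatory column(s): %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")),
          class = "abpm_format_error")
  }
  ts <- parse_timestamp(raw$timestamp)
  num <- function(col) if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, nrow(raw))
  sbp <- num("sbp"); dbp <- num("dbp"); mbp <- num("mbp"); hr <- num("hr")
  ok <- !is.na(ts) & !is.na(sbp) & !is.na(dbp)
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    warn(sprintf("%s: dropped %d malformed row(s) (first at line %d)",
                 basename(path), n_malformed, which(!ok)[1] + 1L))
  }
  readings <- tibble::tibble(timestamp = ts[ok], sbp = sbp[ok], dbp = dbp[ok],
                             mbp = mbp[ok], hr = hr[ok])

  id <- sub("\\.csv$", "", basename(path))
  diary_path <- file.path(dirname(path), paste0(id, ".diary.csv"))
  diary <- NULL
  if (file.exists(diary_path)) {
    draw <- read.csv(diary_path, colClasses = "character", check.names = FALSE)
    if (!all(c("timestamp", "kind") %in% names(draw))) {
      abort(paste0(diary_path, ": diary needs columns timestamp,kind"),
            class = "abpm_format_error")
    }
    diary <- tibble::tibble(timestamp = parse_timestamp(draw$timestamp),
                            kind = draw$kind)
    if (anyNA(diary$timestamp)) {
      abort(paste0(diary_path, ": unparseable diary timestamp"),
            class = "abpm_format_error")
    }
  }
  rec <- abpm_recording(id, readings, diary, config = config)
  attr(rec, "n_malformed") <- n_malformed
  rec
}

#' Write an ABPM recording to the canonical CSV pair
#'
#' Inverse of [read_recording()]: writes `<path>` with header
#' `timestamp,sbp,dbp,mbp,hr` (derived mean arterial pressure and missing
#' heart rate are written as empty cells) and, if the diary is non-empty, the
#' sibling `<stem>.diary.csv`. Reading the written pair reproduces the
#' recording field for field.
#'
#' @param x a valid `abpm_recording`.
#' @param path destination CSV path; the file stem should equal the patient id
#'   for [read_cohort()] to match it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "abpm_recording"))
  validate_recording(x, io_config(require_awakening = FALSE))
  r <- x$readings
  out <- data.frame(
    timestamp = format_timestamp(r$timestamp),
    sbp = r$sbp, dbp = r$dbp,
    mbp = ifelse(r$mbp_derived, "", as.character(r$mbp)),
    hr = ifelse(is.na(r$hr), "", as.character(r$hr)),
    check.names = FALSE)
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write ", path), class = "abpm_io_error")
  if (nrow(x$diary) > 0) {
    dpath <- file.path(dirname(path), paste0(sub("\\.csv$", "", basename(path)),
                                             ".diary.csv"))
    write.csv(data.frame(timestamp = format_timestamp(x$diary$timestamp),
                         kind = x$diary$kind, check.names = FALSE),
              dpath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a patient covariates table
#'
#' Canonical header: `patient_id,age,sex,disease_duration,ledd,
#' cardiovagal_score,adrenergic_score,af_label`. When `af_label` is missing
#' for a patient, both autonomic-testing subscores must be present so the
#' reference diagnosis can be derived via [af_diagnosis()].
#'
#' @param path covariates CSV path.
#' @return a tibble, one row per patient, `af_label` as logical (NA allowed
#'   when subscores are present).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "abpm_io_error")
  }
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("patient_id", "age", "sex", "disease_duration", "ledd")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: missing covariate column(s): %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")),
          class = "abpm_format_error")
  }
  dup <- raw$patient_id[duplicated(raw$patient_id)]
  if (length(dup)) {
    abort(paste0("duplicate patient_id in covariates: ",
                 paste(unique(dup), collapse = ", ")),
          class = "abpm_validation_error")
  }
  getnum <- function(col) if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, nrow(raw))
  lab <- if ("af_label" %in% names(raw)) raw$af_label else rep("", nrow(raw))
  af <- dplyr::case_when(lab %in% c("1", "TRUE", "true") ~ TRUE,
                         lab %in% c("0", "FALSE", "false") ~ FALSE,
                         TRUE ~ NA)
  cov <- tibble::tibble(
    patient_id = raw$patient_id,
    age = getnum("age"),
    sex = toupper(raw$sex),
    disease_duration = getnum("disease_duration"),
    ledd = getnum("ledd"),
    cardiovagal_score = getnum("cardiovagal_score"),
    adrenergic_score = getnum("adrenergic_score"),
    af_label = af)
  if (!all(cov$sex %in% c("M", "F"))) {
    abort(paste0(path, ": sex must be M or F"), class = "abpm_validation_error")
  }
  no_lab <- is.na(cov$af_label) &
    (is.na(cov$cardiovagal_score) | is.na(cov$adrenergic_score))
  if (any(no_lab)) {
    abort(paste0("patients without af_label must carry both autonomic subscores: ",
                 paste(cov$patient_id[no_lab], collapse = ", ")),
          class = "abpm_validation_error")
  }
  cov
}

#' Read a cohort directory
#'
#' Pairs every covariates row with the recording file `<patient_id>.csv` in
#' `recordings_dir`. Unmatched ids on either side (a covariate row without a
#' recording, or an orphan recording file) are an error, as are duplicate ids.
#'
#' @param recordings_dir directory of per-patient recording (and diary) CSVs.
#' @param covariates_path covariates CSV (see [read_covariates()]).
#' @param config an [io_config()] passed to [read_recording()].
#' @return a tibble in covariates-file order: the covariate columns plus a
#'   list-column `recording` of `abpm_recording` objects.
#' @export
read_cohort <- function(recordings_dir, covariates_path, config = io_config()) {
  cov <- read_covariates(covariates_path)
  files <- list.files(recordings_dir, pattern = "\\.csv$")
  rec_ids <- sub("\\.csv$", "", files[!grepl("\\.diary\\.csv$", files)])
  rec_ids <- setdiff(rec_ids, c("covariates", "truth"))  # reserved names
  missing_rec <- setdiff(cov$patient_id, rec_ids)
  if (length(missing_rec)) {
    abort(paste0("no recording file for patient_id: ",
                 paste(missing_rec, collapse = ", ")),
          class = "abpm_validation_error")
  }
  orphan <- setdiff(rec_ids, cov$patient_id)
  if (length(orphan)) {
    abort(paste0("recording without covariates row: ",
                 paste(orphan, collapse = ", ")),
          class = "abpm_validation_error")
  }
  cov$recording <- purrr::map(cov$patient_id, function(id) {
    read_recording(file.path(recordings_dir, paste0(id, ".csv")), config)
  })
  cov
}
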