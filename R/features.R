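#' Feature-extraction configuration
#'
#' Thresholds and window definitions for the circadian blood-pressure
#' parameters. Defaults follow hypertension-society ABPM reference values:
#' daytime load thresholds 135/85 mmHg and night-time 120/70 mmHg (readings at
#' or above the threshold count toward the load), weighted variability called
#' increased above 11 mmHg, a postprandial systolic drop of at least 20 mmHg
#' within 120 min of a meal, morning hypotensive episodes at least 15 mmHg
#' below the 24-h systolic mean between awakening and lunch, and awakening
#' hypotension when an episode falls within 90 min of awakening. All windows
#' are half-open `[a, b)` except the explicitly inclusive postprandial and
#' awakening bounds.
#'
#' @param day_sbp_thr,day_dbp_thr daytime load thresholds (mmHg).
#' @param night_sbp_thr,night_dbp_thr night-time load thresholds (mmHg).
#' @param wbpv_thr weighted-variability "increased" threshold (mmHg).
#' @param pph_drop_thr postprandial systolic drop threshold (mmHg).
#' @param pph_window_min post-meal search window (minutes, inclusive bound).
#' @param hypo_delta hypotensive-episode margin below the 24-h mean (mmHg,
#'   inclusive).
#' @param hypo_aw_window_min awakening-hypotension window (minutes, inclusive).
#' @param lunch_earliest earliest local clock time a diary meal counts as
#'   lunch ("HH:MM").
#' @param lunch_fallback_h morning window length (hours after awakening) used
#'   when no lunch can be identified and `fallback` is allowed.
#' @param fallback_wake,fallback_sleep fixed clock times used for the
#'   day/night split when the diary lacks sleep data and `fallback` is allowed.
#' @param fallback allow the fixed-window fallbacks (flagged in the output).
#' @param sd_single_zero treat a single-reading period standard deviation as 0
#'   instead of an error.
#' @return an `abpm_feature_config` list.
#' @export
feature_config <- function(day_sbp_thr = 135, day_dbp_thr = 85,
                           night_sbp_thr = 120, night_dbp_thr = 70,
                           wbpv_thr = 11,
                           pph_drop_thr = 20, pph_window_min = 120,
                           hypo_delta = 15, hypo_aw_window_min = 90,
                           lunch_earliest = "11:00", lunch_fallback_h = 5,
                           fallback_wake = "07:00", fallback_sleep = "23:00",
                           fallback = FALSE, sd_single_zero = FALSE) {
  structure(as.list(environment()), class = "abpm_feature_config")
}

#' Split a recording into day and night periods
#'
#' Night is every interval `[sleep_onset, next awakening)` from the diary; all
#' other readings are daytime. Nominal day/night durations (used to weight the
#' variability measure) are taken from the diary timestamps themselves:
#' summed awakening-to-sleep and sleep-to-awakening spans. With
#' `config$fallback = TRUE` a diary without sleep data falls back to fixed
#' clock windows (default wake 07:00, sleep 23:00) and the result is flagged.
#'
#' @param recording an `abpm_recording`.
#' @param config a [feature_config()].
#' @return an `abpm_daynight` list: `day`/`night` reading tibbles,
#'   `day_hours`/`night_hours`, and `fallback` flag.
#' @export
split_day_night <- function(recording, config = feature_config()) {
  stopifnot(inherits(recording, "abpm_recording"))
  r <- recording$readings
  diary <- recording$diary
  used_fallback <- FALSE

  sleeps <- diary$timestamp[diary$kind == "sleep_onset"]
  wakes <- diary$timestamp[diary$kind == "awakening"]
  if (length(sleeps) == 0 || length(wakes) == 0) {
    if (!config$fallback) {
      abort(sprintf("patient %s: diary lacks sleep_onset/awakening; enable fallback or supply diary",
                    recording$patient_id), class = "abpm_validation_error")
    }
    used_fallback <- TRUE
    # synthesize fixed clock-time events spanning the recording
    days <- unique(as.Date(r$timestamp, tz = "UTC"))
    days <- sort(c(days, max(days) + 1))
    mk <- function(d, hm) as.POSIXct(paste(d, hm), format = "%Y-%m-%d %H:%M", tz = "UTC")
    wakes <- mk(days, config$fallback_wake)
    sleeps <- mk(days, config$fallback_sleep)
  }

  # night intervals: each sleep onset up to the next awakening (or +Inf)
  night_int <- lapply(sleeps, function(s) {
    nxt <- wakes[wakes > s]
    c(as.numeric(s), if (length(nxt)) as.numeric(min(nxt)) else Inf)
  })
  tnum <- as.numeric(r$timestamp)
  is_night <- rep(FALSE, nrow(r))
  for (iv in night_int) is_night <- is_night | (tnum >= iv[1] & tnum < iv[2])

  day <- r[!is_night, , drop = FALSE]
  night <- r[is_night, , drop = FALSE]
  if (nrow(night) == 0) {
    abort(sprintf("patient %s: no night-time readings", recording$patient_id),
          class = "abpm_validation_error")
  }
  if (nrow(day) == 0) {
    abort(sprintf("patient %s: no daytime readings", recording$patient_id),
          class = "abpm_validation_error")
  }

  # nominal durations from the diary: wake->sleep (day) and sleep->wake (night)
  day_h <- 0; night_h <- 0
  for (w in as.numeric(wakes)) {
    s <- as.numeric(sleeps)[as.numeric(sleeps) > w]
    if (length(s)) day_h <- day_h + (min(s) - w) / 3600
  }
  for (s in as.numeric(sleeps)) {
    w <- as.numeric(wakes)[as.numeric(wakes) > s]
    if (length(w)) night_h <- night_h + (min(w) - s) / 3600
  }
  if (used_fallback) {
    # fixed windows synthesize one extra leading/trailing pair; keep one cycle
    day_h <- parse_hm(config$fallback_sleep) / 60 - parse_hm(config$fallback_wake) / 60
    night_h <- 24 - day_h
  }
  if (day_h <= 0 || night_h <= 0) {
    abort(sprintf("patient %s: degenerate day/night durations from diary",
                  recording$patient_id), class = "abpm_validation_error")
  }
  structure(list(day = day, night = night,
                 day_hours = day_h, night_hours = night_h,
                 fallback = used_fallback),
            class = "abpm_daynight")
}

#' Mean and standard deviation of a pressure component over a period
#'
#' @param readings a readings tibble (rows of one period).
#' @param component `"sbp"`, `"dbp"` or `"mbp"`.
#' @param sd_single_zero with a single reading, return sd 0 instead of erroring.
#' @return named list `mean`, `sd` (mmHg; sample sd, n-1 denominator).
#' @export
period_stats <- function(readings, component = c("sbp", "dbp", "mbp"),
                         sd_single_zero = FALSE) {
  component <- match.arg(component)
  x <- readings[[component]]
  if (length(x) == 0) abort("empty period", class = "abpm_validation_error")
  if (length(x) == 1 && !sd_single_zero) {
    abort("single reading: standard deviation undefined",
          class = "abpm_validation_error")
  }
  list(mean = mean(x), sd = if (length(x) == 1) 0 else sd(x))
}

#' Blood-pressure load
#'
#' Percentage of period readings at or above the period/component reference
#' threshold (day 135/85, night 120/70 mmHg by default).
#'
#' @param split an `abpm_daynight` from [split_day_night()].
#' @param period `"day"` or `"night"`.
#' @param component `"sbp"` or `"dbp"`.
#' @param config a [feature_config()].
#' @return percentage in \[0, 100\].
#' @export
bp_load <- function(split, period = c("day", "night"),
                    component = c("sbp", "dbp"), config = feature_config()) {
  period <- match.arg(period); component <- match.arg(component)
  thr <- switch(paste(period, component),
                "day sbp" = config$day_sbp_thr, "day dbp" = config$day_dbp_thr,
                "night sbp" = config$night_sbp_thr, "night dbp" = config$night_dbp_thr)
  x <- split[[period]][[component]]
  if (length(x) == 0) abort("empty period", class = "abpm_validation_error")
  100 * mean(x >= thr)
}

#' Reverse dipping
#'
#' TRUE when the systolic day-night difference is at most 0 mmHg, i.e. the
#' average nocturnal systolic pressure is at or above the diurnal average (the
#' inverted circadian profile typical of autonomic failure).
#'
#' @inheritParams bp_load
#' @return logical.
#' @export
reverse_dipping <- function(split) {
  d <- period_stats(split$day, "sbp", sd_single_zero = TRUE)$mean
  n <- period_stats(split$night, "sbp", sd_single_zero = TRUE)$mean
  (d - n) <= 0
}

#' Duration-weighted blood-pressure variability
#'
#' The day and night systolic standard deviations averaged with weights equal
#' to the day and night durations:
#' `(sd_day * day_h + sd_night * night_h) / (day_h + night_h)`. The
#' categorical flag is TRUE above `config$wbpv_thr` (11 mmHg).
#'
#' @inheritParams bp_load
#' @return list `value` (mmHg) and `increased` (logical).
#' @export
weighted_bpv <- function(split, config = feature_config()) {
  if (split$day_hours <= 0 || split$night_hours <= 0) {
    abort("degenerate day/night durations", class = "abpm_validation_error")
  }
  sd_d <- period_stats(split$day, "sbp", sd_single_zero = config$sd_single_zero)$sd
  sd_n <- period_stats(split$night, "sbp", sd_single_zero = config$sd_single_zero)$sd
  v <- (sd_d * split$day_hours + sd_n * split$night_hours) /
    (split$day_hours + split$night_hours)
  list(value = v, increased = v > config$wbpv_thr)
}

#' Postprandial hypotension
#'
#' For every diary meal with at least three earlier readings, the reference is
#' the mean systolic pressure of the last three readings before the meal; the
#' drop is the reference minus the minimum systolic value in the window
#' `(meal, meal + 120 min]`. Postprandial hypotension is present when any
#' analysable meal shows a drop of at least 20 mmHg. Meals with fewer than
#' three prior readings (or no reading in the post-meal window) are skipped
#' with a log notice; a recording with no analysable meal is an error.
#'
#' @param recording an `abpm_recording`.
#' @param config a [feature_config()].
#' @return list `pph` (logical) and `meals` (tibble: `meal_time`, `reference`,
#'   `min_post`, `drop`).
#' @export
postprandial_hypotension <- function(recording, config = feature_config()) {
  r <- recording$readings
  meals <- recording$diary$timestamp[recording$diary$kind == "meal"]
  if (length(meals) == 0) {
    abort(sprintf("patient %s: no meal events in diary", recording$patient_id),
          class = "abpm_validation_error")
  }
  rows <- purrr::map(meals, function(m) {
    pre <- r$sbp[r$timestamp < m]
    if (length(pre) < 3) {
      inform(sprintf("patient %s: meal at %s skipped (<3 prior readings)",
                     recording$patient_id, format_timestamp(m)))
      return(NULL)
    }
    post <- r$sbp[r$timestamp > m &
                    r$timestamp <= m + config$pph_window_min * 60]
    if (length(post) == 0) {
      inform(sprintf("patient %s: meal at %s skipped (no post-meal readings)",
                     recording$patient_id, format_timestamp(m)))
      return(NULL)
    }
    ref <- mean(tail(pre, 3))
    tibble::tibble(meal_time = m, reference = ref, min_post = min(post),
                   drop = ref - min(post))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    abort(sprintf("patient %s: no analysable meals", recording$patient_id),
          class = "abpm_validation_error")
  }
  tab <- dplyr::bind_rows(rows)
  list(pph = any(tab$drop >= config$pph_drop_thr), meals = tab)
}

# locate the morning window [awakening, lunch); lunch = first diary meal at or
# after config$lunch_earliest local time (and after awakening)
morning_window <- function(recording, config = feature_config()) {
  wakes <- recording$diary$timestamp[recording$diary$kind == "awakening"]
  if (length(wakes) == 0) {
    abort(sprintf("patient %s: no awakening event", recording$patient_id),
          class = "abpm_validation_error")
  }
  wake <- min(wakes)
  meals <- recording$diary$timestamp[recording$diary$kind == "meal"]
  lunch_cand <- meals[meals > wake &
                        minutes_of_day(meals) >= parse_hm(config$lunch_earliest)]
  fallback <- FALSE
  if (length(lunch_cand)) {
    lunch <- min(lunch_cand)
  } else if (config$fallback) {
    lunch <- wake + config$lunch_fallback_h * 3600
    fallback <- TRUE
  } else {
    abort(sprintf("patient %s: no lunch meal identifiable (enable fallback for a fixed %g-h window)",
                  recording$patient_id, config$lunch_fallback_h),
          class = "abpm_validation_error")
  }
  list(awakening = wake, lunch = lunch, fallback = fallback)
}

#' Morning hypotensive episodes
#'
#' Counts readings between awakening and lunch (half-open window) whose
#' systolic value is at least `hypo_delta` (15) mmHg below the 24-h systolic
#' mean. Lunch is the first diary meal at or after 11:00 local time; with the
#' fallback enabled and no such meal, a fixed awakening + 5 h window is used
#' and flagged.
#'
#' @param recording an `abpm_recording`.
#' @param mean_sbp_24h the recording's 24-h mean systolic pressure (mmHg).
#' @param config a [feature_config()].
#' @return list `n` (count), `times` (POSIXct of qualifying readings),
#'   `awakening`, `lunch`, `fallback`.
#' @export
hypotensive_episodes <- function(recording, mean_sbp_24h,
                                 config = feature_config()) {
  w <- morning_window(recording, config)
  r <- recording$readings
  in_win <- r$timestamp >= w$awakening & r$timestamp < w$lunch
  hit <- in_win & (r$sbp <= mean_sbp_24h - config$hypo_delta)
  list(n = sum(hit), times = r$timestamp[hit],
       awakening = w$awakening, lunch = w$lunch, fallback = w$fallback)
}

#' Awakening hypotension
#'
#' TRUE when at least one morning hypotensive episode occurs within
#' `hypo_aw_window_min` (90) minutes of awakening, bounds inclusive.
#'
#' @param episode_times POSIXct episode timestamps from
#'   [hypotensive_episodes()].
#' @param awakening POSIXct awakening time.
#' @param config a [feature_config()].
#' @return logical.
#' @export
awakening_hypotension <- function(episode_times, awakening,
                                  config = feature_config()) {
  if (length(episode_times) == 0) return(FALSE)
  any(episode_times >= awakening &
        episode_times <= awakening + config$hypo_aw_window_min * 60)
}

# fixed column order of the feature vector; also the discriminant input order
.FEATURE_COLS <- c(
  "mean_sbp_24h", "mean_mbp_24h", "mean_dbp_24h",
  "mean_sbp_day", "mean_mbp_day", "mean_dbp_day",
  "mean_sbp_night", "mean_mbp_night", "mean_dbp_night",
  "sd_sbp_24h", "sd_sbp_day", "sd_sbp_night",
  "load_sbp_day", "load_dbp_day", "load_sbp_night", "load_dbp_night",
  "w_bpv", "pph", "reverse_dipping", "hypo_aw", "n_hypo_ep")

#' Feature column order
#'
#' The fixed column order of the extracted parameter set, which is also the
#' input order of the discriminant model: 24-h/day/night systolic, mean and
#' diastolic averages; 24-h/day/night systolic standard deviations; day and
#' night systolic and diastolic loads; weighted variability; and the
#' postprandial-hypotension, reverse-dipping and awakening-hypotension flags
#' plus the morning hypotensive-episode count.
#'
#' @return character vector of column names.
#' @export
feature_columns <- function() .FEATURE_COLS

#' Extract the circadian blood-pressure parameter set
#'
#' Composes the day/night split, period statistics, loads, weighted
#' variability, postprandial hypotension, and morning hypotensive-episode
#' analysis into one feature row per recording. Deterministic for a fixed
#' recording and configuration, and invariant to the on-file order of rows.
#'
#' @param x an `abpm_recording`, or a cohort tibble from [read_cohort()] (any
#'   data frame with a `recording` list-column).
#' @param config a [feature_config()].
#' @param ... passed between methods.
#' @return a tibble with `patient_id`, the columns of [feature_columns()]
#'   (flags as logical, `n_hypo_ep` integer), and bookkeeping columns
#'   `daynight_fallback`, `lunch_fallback`.
#' @export
extract_features <- function(x, config = feature_config(), ...) {
  UseMethod("extract_features")
}

#' @export
extract_features.abpm_recording <- function(x, config = feature_config(), ...) {
  res <- tryCatch(
    extract_features_one(x, config),
    error = function(e) {
      abort(sprintf("patient %s: %s", x$patient_id, conditionMessage(e)),
            class = "abpm_feature_error", parent = e)
    })
  res
}

extract_features_one <- function(x, config) {
  split <- split_day_night(x, config)
  r <- x$readings
  st <- function(df, comp) period_stats(df, comp, sd_single_zero = config$sd_single_zero)
  s24 <- st(r, "sbp"); m24 <- st(r, "mbp"); d24 <- st(r, "dbp")
  sd_ <- st(split$day, "sbp"); md_ <- st(split$day, "mbp"); dd_ <- st(split$day, "dbp")
  sn_ <- st(split$night, "sbp"); mn_ <- st(split$night, "mbp"); dn_ <- st(split$night, "dbp")
  wb <- weighted_bpv(split, config)
  pph <- postprandial_hypotension(x, config)
  ep <- hypotensive_episodes(x, s24$mean, config)
  aw <- awakening_hypotension(ep$times, ep$awakening, config)
  tibble::tibble(
    patient_id = x$patient_id,
    mean_sbp_24h = s24$mean, mean_mbp_24h = m24$mean, mean_dbp_24h = d24$mean,
    mean_sbp_day = sd_$mean, mean_mbp_day = md_$mean, mean_dbp_day = dd_$mean,
    mean_sbp_night = sn_$mean, mean_mbp_night = mn_$mean, mean_dbp_night = dn_$mean,
    sd_sbp_24h = s24$sd, sd_sbp_day = sd_$sd, sd_sbp_night = sn_$sd,
    load_sbp_day = bp_load(split, "day", "sbp", config),
    load_dbp_day = bp_load(split, "day", "dbp", config),
    load_sbp_night = bp_load(split, "night", "sbp", config),
    load_dbp_night = bp_load(split, "night", "dbp", config),
    w_bpv = wb$value,
    pph = pph$pph,
    reverse_dipping = reverse_dipping(split),
    hypo_aw = aw,
    n_hypo_ep = as.integer(ep$n),
    daynight_fallback = split$fallback,
    lunch_fallback = ep$fallback)
}

#' @export
extract_features.data.frame <- function(x, config = feature_config(), ...) {
  stopifnot("recording" %in% names(x))
  feats <- purrr::map(x$recording, extract_features, config = config)
  dplyr::bind_rows(feats)
}

#' Write a per-patient feature table
#'
#' One row per patient; logical flags serialized as 0/1.
#'
#' @param features tibble from [extract_features()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- as.data.frame(features)
  for (nm in names(out)) if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-patient feature table written by [write_feature_table()]
#'
#' @param path feature CSV path.
#' @return tibble with flags restored to logical.
#' @export
read_feature_table <- function(path) {
  x <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  for (nm in intersect(c("pph", "reverse_dipping", "hypo_aw", "af_label",
                         "daynight_fallback", "lunch_fallback"), names(x))) {
    x[[nm]] <- as.logical(x[[nm]])
  }
  x
}
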