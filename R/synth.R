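#' Synthetic-cohort configuration calibrated to published group statistics
#'
#' Defines the generating conditions for synthetic 24-h ABPM cohorts that
#' mirror the clinical study population: n = 80 Parkinson's disease patients,
#' 36.25% prevalence of autonomic failure, and per-group day/night systolic
#' means, morning hypotensive-episode rates, postprandial-drop probabilities
#' and covariate distributions taken from the published group table
#' (autonomic failure absent: daytime SBP 122 +/- 10, night-time 109 +/- 11,
#' 0.4 episodes, age 61 +/- 10; present: daytime 118 +/- 8, night-time
#' 122 +/- 17, 3.4 episodes, age 67 +/- 10; and so on). Patient-level day and
#' night means are drawn bivariate normal with correlation `day_night_cor`
#' (default 0.5): day and night pressures correlate within a patient, and
#' this value reproduces the published reverse-dipping prevalences
#' (about 11% / 61% analytically) from the group means and SDs alone.
#'
#' @param n_patients cohort size (>= 4).
#' @param af_prevalence probability a patient carries autonomic failure.
#' @param seed master seed; every patient derives an independent substream
#'   from it, so extending the cohort never perturbs earlier patients.
#' @param cadence_min measurement interval (minutes; must divide 24 h).
#' @param wake_time,sleep_time diary wake and sleep clock times ("HH:MM").
#' @param meal_times diary meal clock times ("HH:MM").
#' @param day_night_cor correlation of patient-level day and night means.
#' @param noise_scale multiplier on all within-recording noise standard
#'   deviations; 0 gives the deterministic (noise-free) configuration used
#'   for exact event-recovery checks.
#' @param groups per-group parameter lists (see defaults): `day_sbp` and
#'   `night_sbp` as c(mean, sd) of patient-level means (mmHg), `noise_sd` as
#'   c(mean, sd) of the patient-level within-day reading noise (mmHg),
#'   `hypo_ep_rate` Poisson mean of injected morning dips, `pph_prob`
#'   probability of an injected postprandial trough, `dip_depth` c(min, max)
#'   mmHg below the 24-h mean, `age`/`duration`/`ledd` covariate c(mean, sd),
#'   `female_prob`.
#' @param pulse_pressure c(mean, sd) of the patient-level pulse pressure
#'   (mmHg), truncated at 25.
#' @param pph_trough_drop injected post-meal trough depth below the daytime
#'   level (mmHg).
#' @return an `abpm_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 80, af_prevalence = 0.3625, seed = 1,
                          cadence_min = 15,
                          wake_time = "07:00", sleep_time = "23:00",
                          meal_times = c("08:00", "12:30", "19:30"),
                          day_night_cor = 0.5, noise_scale = 1,
                          groups = list(
                            afneg = list(day_sbp = c(122, 10),
                                         night_sbp = c(109, 11),
                                         noise_sd = c(10, 2.5),
                                         hypo_ep_rate = 0.4,
                                         pph_prob = 0.46,
                                         dip_depth = c(20, 28),
                                         age = c(61, 10),
                                         duration = c(5.5, 3),
                                         ledd = c(657, 326),
                                         female_prob = 0.33),
                            afpos = list(day_sbp = c(118, 8),
                                         night_sbp = c(122, 17),
                                         noise_sd = c(12, 3),
                                         hypo_ep_rate = 3.4,
                                         pph_prob = 0.58,
                                         dip_depth = c(20, 28),
                                         age = c(67, 10),
                                         duration = c(7, 4.5),
                                         ledd = c(694, 403),
                                         female_prob = 0.31)),
                          pulse_pressure = c(45, 5),
                          pph_trough_drop = 30) {
  stopifnot(af_prevalence >= 0, af_prevalence <= 1,
            (24 * 60) %% cadence_min == 0,
            day_night_cor > -1, day_night_cor < 1, noise_scale >= 0,
            all(c("afneg", "afpos") %in% names(groups)))
  for (g in groups) {
    stopifnot(g$day_sbp[2] >= 0, g$night_sbp[2] >= 0, g$hypo_ep_rate >= 0,
              g$pph_prob >= 0, g$pph_prob <= 1, g$dip_depth[1] >= 15)
  }
  structure(as.list(environment()), class = "abpm_cohort_config")
}

# deterministic per-patient substream seed below 2^31
patient_seed <- function(master_seed, i) {
  (as.numeric(master_seed) * 7919 + i * 104729) %% 2147483647
}

#' Generate one synthetic patient
#'
#' Draws the patient's group (Bernoulli on the configured prevalence), the
#' patient-level day/night systolic means (correlated bivariate normal), then
#' builds a full-cadence 24-h series starting at wake time: period baseline
#' plus Gaussian reading noise, Poisson-many rectangular morning dips (1--2
#' slots, configured depth below the 24-h mean) between awakening and lunch,
#' and, with the configured probability, a post-meal trough after lunch or
#' dinner. The daytime baseline is compensated for the injected events so the
#' daytime template mean equals the drawn day mean. Diastolic pressure is the
#' systolic minus a sampled pulse pressure; mean arterial pressure is the
#' usual third-of-pulse formula plus measurement noise. Covariates and
#' autonomic subscores consistent with the group label complete the patient.
#'
#' @param config an [cohort_config()].
#' @param i patient index (drives the RNG substream and the id).
#' @param date calendar date of the recording start.
#' @return list `recording` (`abpm_recording`), `covariates` (one-row
#'   tibble), `truth` (one-row tibble of generating parameters).
#' @export
generate_patient <- function(config, i, date = as.Date("2024-03-01")) {
  withr::with_seed(patient_seed(config$seed, i), {
    af <- runif(1) < config$af_prevalence
    g <- if (af) config$groups$afpos else config$groups$afneg
    ns <- config$noise_scale

    id <- sprintf("P%04d", i)
    cad <- config$cadence_min
    n_slot <- 24 * 60 / cad
    t0 <- as.POSIXct(paste(date, config$wake_time),
                     format = "%Y-%m-%d %H:%M", tz = "UTC")
    times <- t0 + (seq_len(n_slot) - 1) * cad * 60

    wake_min <- parse_hm(config$wake_time)
    sleep_min <- parse_hm(config$sleep_time)
    day_h <- (sleep_min - wake_min) / 60
    night_h <- 24 - day_h
    mod <- minutes_of_day(times)
    is_day <- mod >= wake_min & mod < sleep_min

    # correlated patient-level period means
    z <- rnorm(2)
    rho <- config$day_night_cor
    day_m <- g$day_sbp[1] + g$day_sbp[2] * z[1]
    night_m <- g$night_sbp[1] + g$night_sbp[2] * (rho * z[1] + sqrt(1 - rho^2) * z[2])
    mean24 <- (day_m * day_h + night_m * night_h) / 24

    noise_day <- max(4, rnorm(1, g$noise_sd[1], g$noise_sd[2])) * ns
    noise_night <- 0.8 * noise_day

    template <- ifelse(is_day, day_m, night_m)
    is_event <- rep(FALSE, n_slot)

    # diary
    mk <- function(d, hm) as.POSIXct(paste(d, hm), format = "%Y-%m-%d %H:%M", tz = "UTC")
    meal_ts <- mk(date, config$meal_times)
    diary <- tibble::tibble(
      timestamp = c(t0, meal_ts, mk(date, config$sleep_time), t0 + 24 * 3600),
      kind = c("awakening", rep("meal", length(meal_ts)), "sleep_onset",
               "awakening"))

    # morning dips in [awakening, lunch)
    lunch_idx <- which(minutes_of_day(meal_ts) >= parse_hm("11:00"))[1]
    lunch <- meal_ts[lunch_idx]
    dip_window <- which(times >= t0 & times < lunch & is_day)
    n_dips <- rpois(1, g$hypo_ep_rate)
    dip_slots <- integer(0)
    if (n_dips > 0 && length(dip_window) > 0) {
      n_dips <- min(n_dips, floor(length(dip_window) / 2))
      starts <- sort(sample(dip_window, n_dips))
      for (s in starts) {
        len <- sample(1:2, 1)
        sl <- intersect(s:(s + len - 1), dip_window)
        sl <- setdiff(sl, dip_slots)
        dip_slots <- c(dip_slots, sl)
      }
      depth <- runif(length(dip_slots), g$dip_depth[1], g$dip_depth[2])
      template[dip_slots] <- mean24 - depth
      is_event[dip_slots] <- TRUE
      n_dips <- length(unique(dip_slots))  # slots actually depressed
    } else n_dips <- 0

    # postprandial trough after lunch or dinner (outside the morning window,
    # so injected dip counts stay recoverable)
    pph_injected <- runif(1) < g$pph_prob
    if (pph_injected) {
      post_meals <- meal_ts[minutes_of_day(meal_ts) >= parse_hm("11:00")]
      m <- post_meals[sample(length(post_meals), 1)]
      win <- which(times > m & times <= m + 120 * 60 & !is_event)
      if (length(win) >= 2) {
        sl <- win[1:2 + sample(0:max(0, length(win) - 3), 1)]
        sl <- sl[!is.na(sl)]
        template[sl] <- day_m - config$pph_trough_drop
        is_event[sl] <- TRUE
      } else pph_injected <- FALSE
    }

    # compensate non-event daytime slots so the day template mean stays day_m
    free <- is_day & !is_event
    if (any(is_event & is_day) && any(free)) {
      target_sum <- day_m * sum(is_day)
      template[free] <- (target_sum - sum(template[is_day & is_event])) / sum(free)
    }

    sbp <- template + rnorm(n_slot, 0, ifelse(is_day, noise_day, noise_night))
    sbp <- pmin(pmax(sbp, 70), 260)
    pp_pat <- max(25, rnorm(1, config$pulse_pressure[1], config$pulse_pressure[2]))
    pp <- pmax(20, pp_pat + rnorm(n_slot, 0, 3 * ns))
    dbp <- pmax(25, sbp - pp)
    mbp <- pmin(pmax(dbp + (sbp - dbp) / 3 + rnorm(n_slot, 0, 1.5 * ns), dbp), sbp)
    hr <- round(pmax(40, rnorm(n_slot, 72, 6)))

    readings <- tibble::tibble(timestamp = times,
                               sbp = round(sbp, 1), dbp = round(dbp, 1),
                               mbp = round(mbp, 1), hr = hr)
    rec <- abpm_recording(id, readings, diary)

    # covariates + autonomic subscores consistent with the group
    if (af) {
      repeat {
        cv <- sample(0:3, 1, prob = c(0.25, 0.3, 0.3, 0.15))
        ad <- sample(0:4, 1, prob = c(0.1, 0.25, 0.3, 0.25, 0.1))
        if (cv + ad >= 2) break
      }
    } else {
      pick <- sample(1:3, 1, prob = c(0.5, 0.25, 0.25))
      cv <- c(0, 0, 1)[pick]; ad <- c(0, 1, 0)[pick]
    }
    covariates <- tibble::tibble(
      patient_id = id,
      age = round(min(90, max(35, rnorm(1, g$age[1], g$age[2])))),
      sex = if (runif(1) < g$female_prob) "F" else "M",
      disease_duration = round(max(0.5, rnorm(1, g$duration[1], g$duration[2])), 1),
      ledd = round(max(50, rnorm(1, g$ledd[1], g$ledd[2]))),
      cardiovagal_score = cv, adrenergic_score = ad,
      af_label = af)

    truth <- tibble::tibble(
      patient_id = id, af = af,
      day_mean = day_m, night_mean = night_m, mean24 = mean24,
      noise_sd_day = noise_day, noise_sd_night = noise_night,
      n_dips = n_dips, pph_injected = pph_injected)

    list(recording = rec, covariates = covariates, truth = truth)
  })
}

#' Generate a synthetic ABPM cohort
#'
#' Independent per-patient draws under [generate_patient()]; fully
#' reproducible from the master seed, with per-patient substreams so cohorts
#' of different sizes agree on their common patients.
#'
#' @param config an [cohort_config()].
#' @return an `abpm_synth_cohort`: `recordings` (list), `covariates` (tibble
#'   with `af_label`), `truth` (tibble of generating parameters), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "abpm_cohort_config"))
  if (config$n_patients < 4) {
    abort("need at least 4 patients (both classes downstream)",
          class = "abpm_validation_error")
  }
  pats <- purrr::map(seq_len(config$n_patients), function(i)
    generate_patient(config, i))
  structure(list(recordings = purrr::map(pats, "recording"),
                 covariates = dplyr::bind_rows(purrr::map(pats, "covariates")),
                 truth = dplyr::bind_rows(purrr::map(pats, "truth")),
                 config = config),
            class = "abpm_synth_cohort")
}

#' @export
print.abpm_synth_cohort <- function(x, ...) {
  cat(sprintf("<abpm_synth_cohort> n=%d (%d AF+ / %d AF-), seed %s\n",
              length(x$recordings), sum(x$covariates$af_label),
              sum(!x$covariates$af_label), format(x$config$seed)))
  invisible(x)
}

# group labels only, same per-patient substream draw as generate_patient();
# used for cheap large-n prevalence checks
af_labels_only <- function(n, af_prevalence, seed) {
  vapply(seq_len(n), function(i)
    withr::with_seed(patient_seed(seed, i), runif(1) < af_prevalence),
    logical(1))
}

#' Write a synthetic cohort as a cohort directory
#'
#' Emits per-patient recording and diary CSVs plus `covariates.csv` in the
#' canonical formats read by [read_cohort()], and `truth.csv` with the
#' generating parameters.
#'
#' @param cohort an `abpm_synth_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abpm_synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(dir, paste0(rec$patient_id, ".csv")))
  }
  cov <- as.data.frame(cohort$covariates)
  cov$af_label <- as.integer(cov$af_label)
  write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(as.data.frame(cohort$truth), file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Convert a synthetic cohort to the labelled feature table
#'
#' Runs [extract_features()] on every recording and joins the covariates
#' (including the autonomic-failure label), giving the table consumed by
#' [fit_lda()].
#'
#' @param cohort an `abpm_synth_cohort`.
#' @param config a [feature_config()].
#' @return tibble: covariates + feature columns per patient.
#' @export
cohort_features <- function(cohort, config = feature_config()) {
  feats <- dplyr::bind_rows(purrr::map(cohort$recordings, extract_features,
                                       config = config))
  dplyr::inner_join(cohort$covariates, feats, by = "patient_id")
}
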