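# In-code fixtures: 24-h recordings at 15-min cadence starting at 07:00 wake,
# sleep 23:00, meals 08:00 / 12:30 / 19:30. With 96 slots, slots 1:64 are
# daytime and 65:96 night.

fix_time <- function(hm = "07:00", date = "2024-03-01") {
  as.POSIXct(paste(date, hm), format = "%Y-%m-%d %H:%M", tz = "UTC")
}

make_readings <- function(sbp, start = fix_time(), cadence_min = 15,
                          dbp = sbp - 45, mbp = NULL, hr = NULL) {
  df <- tibble::tibble(
    timestamp = start + (seq_along(sbp) - 1) * cadence_min * 60,
    sbp = sbp, dbp = dbp)
  if (!is.null(mbp)) df$mbp <- mbp
  if (!is.null(hr)) df$hr <- hr
  df
}

std_diary <- function(date = "2024-03-01", wake = "07:00", sleep = "23:00",
                      meals = c("08:00", "12:30", "19:30")) {
  tibble::tibble(
    timestamp = c(fix_time(wake, date), fix_time(meals, date),
                  fix_time(sleep, date), fix_time(wake, date) + 24 * 3600),
    kind = c("awakening", rep("meal", length(meals)), "sleep_onset",
             "awakening"))
}

make_recording <- function(sbp = rep(120, 96), id = "T001",
                           diary = std_diary(), dbp = sbp - 45, ...) {
  abpm_recording(id, make_readings(sbp, dbp = dbp), diary, ...)
}

# split object built directly, for operations that only need period readings
make_split <- function(day_sbp, night_sbp, day_hours = 16, night_hours = 8) {
  structure(list(day = tibble::tibble(sbp = day_sbp, dbp = day_sbp - 45),
                 night = tibble::tibble(sbp = night_sbp, dbp = night_sbp - 45),
                 day_hours = day_hours, night_hours = night_hours,
                 fallback = FALSE),
            class = "abpm_daynight")
}

# independent Clopper-Pearson oracle: direct root-finding on binomial tails
cp_ci_oracle <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  c(lo, hi)
}

# brute-force pairwise concordance (ties count 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random labelled feature table with two well-separated Gaussian classes
random_cohort_table <- function(n1 = 15, n0 = 25, p = 3, delta = 2,
                                seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n0 * p), n0), matrix(rnorm(n1 * p, delta), n1))
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- paste0("f", seq_len(p))
    df$af_label <- rep(c(FALSE, TRUE), c(n0, n1))
    df
  })
}
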