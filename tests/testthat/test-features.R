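test_that("day/night split follows the diary over half-open windows", {
  rec <- make_recording(sbp = rep(120, 96))   # wake 07:00, sleep 23:00
  sp <- split_day_night(rec)
  expect_equal(nrow(sp$day), 64)
  expect_equal(nrow(sp$night), 32)
  expect_equal(sp$day_hours, 16)
  expect_equal(sp$night_hours, 8)
  expect_false(sp$fallback)
  # the 23:00 reading itself is night (closed lower bound)
  expect_true(fix_time("23:00") %in% sp$night$timestamp)
  expect_false(fix_time("23:00") %in% sp$day$timestamp)
})

test_that("fixed clock-time fallback reproduces the explicit diary split and is flagged", {
  sbp <- round(rnorm(96, 120, 8))
  with_diary <- split_day_night(make_recording(sbp = sbp))
  no_diary <- abpm_recording("ND", make_readings(sbp), diary = NULL,
                             config = io_config(require_awakening = FALSE))
  expect_error(split_day_night(no_diary), class = "abpm_validation_error")
  fb <- split_day_night(no_diary, feature_config(fallback = TRUE))
  expect_true(fb$fallback)
  expect_equal(fb$day$sbp, with_diary$day$sbp)
  expect_equal(fb$night$sbp, with_diary$night$sbp)
  expect_equal(fb$day_hours, 16)
  expect_equal(fb$night_hours, 8)
})

test_that("a split with an empty period is rejected", {
  # readings confined to daytime hours of two consecutive days (span 27 h)
  t <- c(fix_time("08:00") + (0:40) * 15 * 60,
         fix_time("08:00") + 24 * 3600 + (0:40) * 15 * 60)
  r <- tibble::tibble(timestamp = t, sbp = 120, dbp = 75)
  diary <- tibble::tibble(
    timestamp = c(fix_time("07:00"), fix_time("23:30"),
                  fix_time("07:00") + 24 * 3600),
    kind = c("awakening", "sleep_onset", "awakening"))
  rec <- abpm_recording("DD", r, diary, validate = FALSE)
  expect_error(split_day_night(rec), "night",
               class = "abpm_validation_error")
})

test_that("period statistics use the sample standard deviation", {
  expect_equal(period_stats(tibble::tibble(sbp = c(120, 120, 120)), "sbp"),
               list(mean = 120, sd = 0))
  expect_equal(period_stats(tibble::tibble(sbp = c(110, 120, 130)), "sbp"),
               list(mean = 120, sd = 10))
  expect_error(period_stats(tibble::tibble(sbp = numeric(0)), "sbp"),
               class = "abpm_validation_error")
  expect_error(period_stats(tibble::tibble(sbp = 120), "sbp"),
               class = "abpm_validation_error")
  expect_equal(period_stats(tibble::tibble(sbp = 120), "sbp",
                            sd_single_zero = TRUE),
               list(mean = 120, sd = 0))
})

test_that("blood-pressure load counts readings at or above the threshold", {
  sp <- make_split(day_sbp = c(130, 140, 136), night_sbp = c(100, 100))
  expect_equal(bp_load(sp, "day", "sbp"), 100 * 2 / 3)
  expect_equal(bp_load(make_split(c(120, 130), c(100)), "day", "sbp"), 0)
  expect_equal(bp_load(make_split(c(135, 135), c(100)), "day", "sbp"), 100)
  # night thresholds 120/70
  expect_equal(bp_load(make_split(c(130), c(120, 119)), "night", "sbp"), 50)
})

test_that("reverse dipping is a day-night difference at or below zero", {
  expect_true(reverse_dipping(make_split(rep(118, 3), rep(122, 3))))
  expect_false(reverse_dipping(make_split(rep(122, 3), rep(109, 3))))
  expect_true(reverse_dipping(make_split(rep(120, 3), rep(120, 3))))
})

test_that("weighted variability is the duration-weighted average of period SDs", {
  # sd 10 and 14 over 16 h / 8 h -> (160 + 112) / 24
  sp <- make_split(c(110, 120, 130), c(106, 120, 134))
  wb <- weighted_bpv(sp)
  expect_equal(wb$value, (10 * 16 + 14 * 8) / 24)
  expect_true(wb$increased)
  # equal SDs: duration-independent
  for (h in list(c(16, 8), c(12, 12), c(20, 4))) {
    sp2 <- make_split(c(108, 120, 132), c(98, 110, 122), h[1], h[2])
    expect_equal(weighted_bpv(sp2)$value, 12)
  }
  sp3 <- make_split(rep(120, 3), rep(110, 3))
  expect_equal(weighted_bpv(sp3)$value, 0)
  expect_false(weighted_bpv(sp3)$increased)
  sp3$day_hours <- 0
  expect_error(weighted_bpv(sp3), class = "abpm_validation_error")
})

test_that("weighted variability lies between the two period SDs", {
  for (s in 1:20) {
    withr::with_seed(s, {
      sp <- make_split(rnorm(10, 120, runif(1, 1, 15)),
                       rnorm(8, 110, runif(1, 1, 15)),
                       day_hours = runif(1, 10, 20))
      sp$night_hours <- 24 - sp$day_hours
      sds <- c(sd(sp$day$sbp), sd(sp$night$sbp))
      v <- weighted_bpv(sp)$value
      expect_gte(v, min(sds)); expect_lte(v, max(sds))
    })
  }
})

test_that("postprandial hypotension uses the last three pre-meal readings", {
  # slots 1:96 from 07:00; breakfast 08:00 follows slots 1:4 (07:00-07:45)
  sbp <- rep(130, 96)
  sbp[2:4] <- c(130, 128, 132)          # reference = 130
  sbp[7] <- 108                          # 08:30, within (08:00, 10:00]
  pp <- postprandial_hypotension(make_recording(sbp = sbp))
  expect_true(pp$pph)
  expect_equal(pp$meals$drop[1], 22)
  # boundary: drop of exactly 20 qualifies
  sbp[7] <- 110
  expect_true(postprandial_hypotension(make_recording(sbp = sbp))$pph)
  # no post-meal reading below reference: negative
  expect_false(postprandial_hypotension(make_recording(sbp = rep(130, 96)))$pph)
})

test_that("meals without three prior readings are skipped; none analysable is an error", {
  # meal 15 min after recording start: only 1 prior reading
  diary <- std_diary(meals = c("07:15", "12:30", "19:30"))
  expect_message(pp <- postprandial_hypotension(make_recording(diary = diary)),
                 "skipped")
  expect_equal(nrow(pp$meals), 2)
  no_meals <- std_diary()[std_diary()$kind != "meal", ]
  expect_error(postprandial_hypotension(make_recording(diary = no_meals)),
               class = "abpm_validation_error")
})

test_that("morning hypotensive episodes are readings at least 15 mmHg under the 24-h mean", {
  sbp <- rep(125, 96)
  # morning window is [07:00 awakening, 12:30 lunch): slots 1:22
  sbp[5] <- 100; sbp[10] <- 110; sbp[15] <- 104
  rec <- make_recording(sbp = sbp)
  ep <- hypotensive_episodes(rec, mean_sbp_24h = 120)
  expect_equal(ep$n, 2)                  # threshold 105: 100 and 104 qualify
  expect_equal(ep$lunch, fix_time("12:30"))
  # boundary: exactly mean - 15 is counted (threshold 110 catches all three)
  expect_equal(hypotensive_episodes(rec, mean_sbp_24h = 125)$n, 3)
  expect_equal(hypotensive_episodes(make_recording(), 120)$n, 0)
  # a dip after lunch is outside the window
  sbp2 <- rep(125, 96); sbp2[30] <- 80
  expect_equal(hypotensive_episodes(make_recording(sbp = sbp2), 120)$n, 0)
})

test_that("lunch falls back to a fixed window only when allowed", {
  diary <- std_diary(meals = c("08:00"))   # no meal at/after 11:00
  rec <- make_recording(diary = diary)
  expect_error(hypotensive_episodes(rec, 120),
               class = "abpm_validation_error")
  ep <- hypotensive_episodes(rec, 120, feature_config(fallback = TRUE))
  expect_true(ep$fallback)
  expect_equal(ep$lunch, fix_time("12:00"))   # awakening + 5 h
})

test_that("awakening hypotension window is inclusive at 90 minutes", {
  wake <- fix_time("07:00")
  expect_true(awakening_hypotension(wake + 30 * 60, wake))
  expect_true(awakening_hypotension(wake + 90 * 60, wake))
  expect_false(awakening_hypotension(wake + 91 * 60, wake))
  expect_false(awakening_hypotension(as.POSIXct(character(), tz = "UTC"), wake))
})

test_that("a flat recording yields zero variability, zero loads and no events", {
  ft <- extract_features(make_recording(sbp = rep(100, 96),
                                        dbp = rep(65, 96)))
  expect_equal(ft$sd_sbp_24h, 0)
  expect_equal(ft$sd_sbp_day, 0)
  expect_equal(ft$w_bpv, 0)
  expect_equal(ft$load_sbp_day + ft$load_dbp_day +
                 ft$load_sbp_night + ft$load_dbp_night, 0)
  expect_false(ft$pph)
  expect_false(ft$hypo_aw)
  expect_equal(ft$n_hypo_ep, 0L)
  # equal day and night means sit on the reverse-dipping boundary (<= 0)
  expect_true(ft$reverse_dipping)
})

test_that("engineered morning dips and nocturnal excess are recovered", {
  sbp <- c(rep(100, 64), rep(110, 32))
  sbp[c(5, 9, 13)] <- 70                 # three morning dips before lunch
  ft <- extract_features(make_recording(sbp = sbp))
  expect_equal(ft$n_hypo_ep, 3L)
  expect_true(ft$reverse_dipping)
  expect_true(ft$hypo_aw)                # dip at slot 5 = 08:00, within 90 min
  expect_equal(ft$mean_sbp_night, 110)
})

test_that("extraction is invariant to the on-file order of readings", {
  dir <- withr::local_tempdir()
  sbp <- round(rnorm(96, 120, 10))
  rec <- make_recording(sbp = sbp, id = "S1")
  path <- file.path(dir, "S1.csv")
  write_recording(rec, path)
  rows <- readLines(path)
  writeLines(c(rows[1], rev(rows[-1])), path)
  expect_equal(extract_features(read_recording(path)), extract_features(rec))
})

test_that("shifting all systolic values shifts means only", {
  for (s in 1:5) {
    sbp <- withr::with_seed(s, round(rnorm(96, 125, 10)))
    sbp[c(4, 8)] <- sbp[c(4, 8)] - 30
    a <- extract_features(make_recording(sbp = sbp, dbp = sbp - 45))
    b <- extract_features(make_recording(sbp = sbp + 7, dbp = sbp - 45 + 7))
    expect_equal(b$mean_sbp_24h, a$mean_sbp_24h + 7)
    expect_equal(b$mean_sbp_night, a$mean_sbp_night + 7)
    expect_equal(b$sd_sbp_24h, a$sd_sbp_24h)
    expect_equal(b$sd_sbp_day, a$sd_sbp_day)
    expect_equal(b$w_bpv, a$w_bpv)
    expect_equal(b$reverse_dipping, a$reverse_dipping)
    expect_equal(b$n_hypo_ep, a$n_hypo_ep)   # threshold is mean-relative
  }
})

test_that("adding a supra-threshold day reading cannot decrease the day load", {
  for (s in 1:10) {
    day <- withr::with_seed(s, rnorm(20, 130, 12))
    sp <- make_split(day, rnorm(8, 110, 8))
    sp_plus <- make_split(c(day, 150), sp$night$sbp)
    expect_gte(bp_load(sp_plus, "day", "sbp"), bp_load(sp, "day", "sbp"))
  }
})

test_that("feature table round-trips through 0/1 CSV serialization", {
  dir <- withr::local_tempdir()
  ft <- extract_features(make_recording(sbp = round(rnorm(96, 120, 12))))
  p <- file.path(dir, "features.csv")
  write_feature_table(ft, p)
  raw <- read.csv(p)
  expect_true(all(raw$pph %in% 0:1))
  back <- read_feature_table(p)
  expect_equal(back$reverse_dipping, ft$reverse_dipping)
  expect_equal(back$mean_sbp_24h, ft$mean_sbp_24h)
})
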