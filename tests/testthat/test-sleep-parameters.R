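test_that("noon windows partition a 7-day midnight-start recording", {
  d <- make_decoded(sleep_intervals = list())
  sp <- split_noon_days(d)
  expect_equal(sort(unique(sp$window)), 0:7)
  counts <- table(sp$window)
  expect_equal(as.integer(counts[as.character(1:6)]), rep(1440L, 6))
  expect_equal(as.integer(counts[c("0", "7")]), c(720L, 720L))
  # minute 720 of day 1 is window 1, offset 0
  expect_equal(sp$window[sp$day_index == 1 & sp$minute_of_day == 720], 1)
  expect_equal(sp$offset[sp$day_index == 1 & sp$minute_of_day == 720], 0)
  # no overlap: every minute in exactly one window
  expect_equal(nrow(sp), 7 * 1440)
  expect_false(anyDuplicated(paste(sp$window, sp$offset)) > 0)
})

test_that("the longest merged sleep block wins, split by gaps >= the merge tolerance", {
  lab <- c(rep(TRUE, 300), rep(FALSE, 120), rep(TRUE, 400), rep(FALSE, 100))
  expect_equal(find_spt_window(lab), c(420L, 820L))

  lab <- c(rep(FALSE, 50), rep(TRUE, 200), rep(FALSE, 20), rep(TRUE, 250),
           rep(FALSE, 100))
  spt <- find_spt_window(lab)
  expect_equal(spt, c(50L, 520L))                 # merged: 200+20+250 = 470
  b <- wake_bouts(lab, spt)
  expect_equal(nrow(b), 1)
  expect_equal(b$length, 20L)

  expect_null(find_spt_window(rep(FALSE, 500)))
})

test_that("SPT ties break to the earliest block and edges are trimmed to sleep", {
  lab <- c(rep(FALSE, 10), rep(TRUE, 100), rep(FALSE, 80), rep(TRUE, 100),
           rep(FALSE, 30))
  spt <- find_spt_window(lab)
  expect_equal(spt, c(10L, 110L))
  # window starts and ends in sleep
  expect_true(lab[spt[1] + 1] && lab[spt[2]])
})

test_that("onset clock transform puts 1 am at 25 h", {
  expect_identical(onset_clock_transform(780), 25)     # 01:00
  expect_equal(onset_clock_transform(690), 23.5)       # 23:30
  expect_equal(onset_clock_transform(720), 24)         # midnight
  expect_equal(onset_clock_transform(0), 12)
  expect_error(onset_clock_transform(1440), class = "actisleep_error")
})

test_that("wake bouts never touch the SPT boundary and vanish for pure sleep", {
  lab <- rep(TRUE, 300)
  spt <- find_spt_window(lab)
  expect_equal(nrow(wake_bouts(lab, spt)), 0)

  lab <- c(rep(TRUE, 100), rep(FALSE, 10), rep(TRUE, 50), rep(FALSE, 5),
           rep(TRUE, 100))
  spt <- find_spt_window(lab)
  b <- wake_bouts(lab, spt)
  expect_equal(b$length, c(10L, 5L))
  expect_true(all(b$start > spt[1] & b$start + b$length < spt[2]))
})

test_that("night parameters follow the duration and efficiency formulas", {
  np <- night_parameters(c(600L, 1080L),
                         data.frame(start = c(700L, 900L),
                                    length = c(20L, 10L)))
  expect_equal(np$spt_len_h, 8)
  expect_equal(np$sleep_duration_h, 7.5)
  expect_equal(np$sleep_efficiency, 0.9375)
  expect_true(np$valid)
  expect_equal(np$sleep_duration_h, np$spt_len_h * np$sleep_efficiency,
               tolerance = 1e-12)

  short <- night_parameters(c(600L, 770L), data.frame(start = integer(0),
                                                      length = integer(0)))
  expect_equal(short$spt_len_h, 170 / 60)
  expect_false(short$valid)                       # < 3 h

  pure <- night_parameters(c(600L, 1080L), data.frame(start = integer(0),
                                                      length = integer(0)))
  expect_equal(pure$sleep_efficiency, 1)
})

test_that("adding a wake bout shrinks duration and efficiency but not the SPT", {
  spt <- c(600L, 1080L)
  b0 <- data.frame(start = 700L, length = 15L)
  b1 <- rbind(b0, data.frame(start = 800L, length = 10L))
  n0 <- night_parameters(spt, b0); n1 <- night_parameters(spt, b1)
  expect_lt(n1$sleep_duration_h, n0$sleep_duration_h)
  expect_lt(n1$sleep_efficiency, n0$sleep_efficiency)
  expect_equal(n1$spt_len_h, n0$spt_len_h)
})

test_that("weekend nights are those anchored on Friday or Saturday noons", {
  expect_true(weekend_classification(6))    # Friday (1 = Sunday)
  expect_true(weekend_classification(7))    # Saturday
  expect_false(weekend_classification(1))   # Sunday noon -> weekday night
  expect_false(weekend_classification(4))
  # any 7-day recording contains both weekend and weekday anchors
  for (start in 1:7) {
    dows <- ((start - 1 + 0:6) %% 7) + 1
    cls <- weekend_classification(dows)
    expect_true(any(cls) && any(!cls))
  }
})

test_that("scored nights recover constructed schedules to the minute", {
  # night 1: 23:00 -> 07:00 with a 20-min bout at 02:00
  # night 2 (anchored day-2 noon): 00:30 -> 08:00 on day 3, unbroken
  d <- make_decoded(sleep_intervals = list(c(1380L, 1860L), c(2910L, 3360L)))
  # carve the bout out of night 1 (absolute minutes 1560..1579)
  d$sleep[1561:1580] <- FALSE
  nights <- score_nights(d)
  n1 <- nights[nights$sleep_day_index == 1, ]
  expect_equal(n1$onset_clock, 23)
  expect_equal(n1$wakeup_clock, 31)                # 07:00 next morning
  expect_equal(n1$n_bouts, 1L)
  expect_equal(n1$sleep_duration_h, 460 / 60)
  expect_equal(n1$sleep_efficiency, 460 / 480)
  n2 <- nights[nights$sleep_day_index == 2, ]
  expect_equal(n2$onset_clock, 24.5)
  expect_equal(n2$sleep_duration_h, 7.5)
  expect_equal(n2$sleep_efficiency, 1)
})

test_that("nights in partial windows are invalid when the SPT is truncated", {
  # sleep runs to the very end of the recording (window 7 is partial)
  d <- make_decoded(sleep_intervals = list(c(9600L, 10080L)))
  nights <- score_nights(d)
  n7 <- nights[nights$sleep_day_index == 7, ]
  expect_false(n7$valid)
})

test_that("subject aggregation enforces the 3-valid-night rule and NA side-means", {
  night <- function(sid, idx, onset, valid = TRUE, weekend = FALSE) {
    data.frame(subject_id = sid, sleep_day_index = idx,
               is_weekend_night = weekend, partial_window = FALSE,
               spt_start_min = 660L, spt_end_min = 1140L,
               onset_clock = onset, wakeup_clock = onset + 8,
               n_bouts = 0L, bout_min = 0L, spt_len_h = 8,
               sleep_duration_h = 8, sleep_efficiency = 1, valid = valid)
  }
  nights <- rbind(night("A", 1, 23), night("A", 2, 24), night("A", 3, 25),
                  night("B", 1, 23), night("B", 2, 24),
                  night("B", 3, 26, valid = FALSE))
  s <- aggregate_subjects(nights)
  expect_true(s$included[s$subject_id == "A"])
  expect_false(s$included[s$subject_id == "B"])    # only 2 valid nights
  expect_equal(s$mean_onset_clock[s$subject_id == "A"], 24)
  expect_true(is.na(s$mean_onset_weekend[s$subject_id == "A"]))
  expect_false(is.na(s$mean_onset_weekday[s$subject_id == "A"]))
})
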