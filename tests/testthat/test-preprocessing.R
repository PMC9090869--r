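test_that("each masking rule fires on its own and leaves clean minutes alone", {
  m <- make_minutes(mims = 3.2)
  m$quality_flag_count[1] <- 1L        # flag
  m$mims_triaxial[2] <- -0.01          # sentinel
  m$wear_pred[3] <- "non-wear"         # non-wear
  clean <- mask_invalid_minutes(m)
  expect_true(all(clean$missing[1:3]))
  expect_false(any(clean$missing[4:1440]))
  expect_equal(clean$value[4], 3.2)
  expect_true(all(is.na(clean$value[1:3])))
})

test_that("masking is idempotent: re-masking the masked table marks the same set", {
  m <- make_minutes(mims = runif(1440, 0, 5))
  m$wear_pred[100:180] <- "non-wear"
  m$quality_flag_count[500] <- 2L
  clean <- mask_invalid_minutes(m)
  # represent the masked series as a table again (missing as sentinel)
  m2 <- m
  m2$mims_triaxial <- ifelse(clean$missing, -0.01, clean$value)
  clean2 <- mask_invalid_minutes(m2)
  expect_identical(clean2$missing, clean$missing)
  expect_identical(clean2$value, clean$value)
})

test_that("missing intervals respect the 60-minute threshold and run structure", {
  m <- make_minutes(mims = 1)
  m$wear_pred[101:159] <- "non-wear"                 # 59-minute run
  iv <- missing_intervals(mask_invalid_minutes(m))
  expect_equal(nrow(iv), 0)

  m$wear_pred[101:160] <- "non-wear"                 # 60-minute run
  iv <- missing_intervals(mask_invalid_minutes(m))
  expect_equal(iv$length, 60L)
  expect_equal(iv$start, 101L)

  # runs of 90 and 30 separated by wear -> only the 90 qualifies
  m <- make_minutes(mims = 1)
  m$wear_pred[201:290] <- "non-wear"
  m$wear_pred[401:430] <- "non-wear"
  iv <- missing_intervals(mask_invalid_minutes(m))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$length, 90L)
})

test_that("wear-day validity is strictly more than 16 hours", {
  wear_day <- function(wear_min) {
    m <- make_minutes(mims = 1)
    if (wear_min < 1440) m$wear_pred[(wear_min + 1):1440] <- "non-wear"
    flag_valid_days(mask_invalid_minutes(m))$valid_day
  }
  expect_false(wear_day(960))
  expect_true(wear_day(961))
  expect_true(wear_day(1440))
})

test_that("imputation eligibility needs at least 4 valid days", {
  vd <- data.frame(subject_id = rep(c("A", "B", "C"), each = 7),
                   day_index = rep(1:7, 3),
                   wear_min = 1440,
                   valid_day = c(rep(TRUE, 4), rep(FALSE, 3),   # A: 4
                                 rep(TRUE, 3), rep(FALSE, 4),   # B: 3
                                 rep(TRUE, 7)))                 # C: 7
  el <- imputation_eligibility(vd)
  expect_equal(el$eligible[el$subject_id == "A"], TRUE)
  expect_equal(el$eligible[el$subject_id == "B"], FALSE)
  expect_equal(el$eligible[el$subject_id == "C"], TRUE)
})

test_that("minute-profile imputation averages donors at the same minute of day", {
  m <- make_minutes(n_days = 5, mims = 2)
  # values 10 and 20 at minute 600 on days 1 and 2; 2 elsewhere
  m$mims_triaxial[m$day_index == 1 & m$minute_of_day == 600] <- 10
  m$mims_triaxial[m$day_index == 2 & m$minute_of_day == 600] <- 20
  m$mims_triaxial[m$day_index == 4 & m$minute_of_day == 600] <- 99
  # 60+ minute nonwear intervals covering minute 600 on days 3, 4 and 5,
  # so days 1 and 2 are the only donors for that minute of day
  m$wear_pred[m$day_index == 3 & m$minute_of_day %in% 570:629] <- "non-wear"
  m$wear_pred[m$day_index == 4 & m$minute_of_day %in% 560:649] <- "non-wear"
  m$wear_pred[m$day_index == 5 & m$minute_of_day %in% 570:629] <- "non-wear"
  clean <- mask_invalid_minutes(m)
  imp <- impute_missing(clean)
  got <- imp$value[imp$day_index == 3 & imp$minute_of_day == 600]
  expect_equal(got, mean(c(10, 20)))   # masked minutes are never donors
  expect_true(all(!is.na(imp$value)))
})

test_that("imputation never alters non-missing minutes and is identity without missingness", {
  m <- make_minutes(n_days = 4, mims = runif(4 * 1440, 0, 6))
  clean <- mask_invalid_minutes(m)
  imp <- impute_missing(clean)
  expect_equal(imp$value, clean$value)

  m$wear_pred[200:400] <- "non-wear"
  clean <- mask_invalid_minutes(m)
  imp <- impute_missing(clean)
  expect_equal(imp$value[!clean$missing], clean$value[!clean$missing])
})

test_that("sub-threshold missing runs are zeroed, not imputed", {
  m <- make_minutes(n_days = 4, mims = 5)
  m$quality_flag_count[300:310] <- 1L     # 11-minute missing run
  imp <- impute_missing(mask_invalid_minutes(m))
  expect_equal(unique(imp$value[300:310]), 0)
  expect_false(any(imp$imputed[300:310]))
})

test_that("seeded zero-inflated imputation is reproducible", {
  m <- make_minutes(n_days = 5, mims = rep(c(0, 4, 8, 0, 2), 288 * 5))
  m$wear_pred[m$day_index == 2 & m$minute_of_day %in% 100:220] <- "non-wear"
  clean <- mask_invalid_minutes(m)
  a <- impute_missing(clean, method = "zip_model", seed = 11)
  b <- impute_missing(clean, method = "zip_model", seed = 11)
  c2 <- impute_missing(clean, method = "zip_model", seed = 12)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c2$value))
})
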