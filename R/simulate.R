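# Synthetic accelerometer cohort with known true sleep schedules.
#
# Emulates the structure the analysis assumes in NHANES-style 24-h wrist
# accelerometry: 7 consecutive noon-anchored sleep days of minute-level MIMS
# per subject, age/sex/race-structured sleep schedules, device non-wear
# blocks, quality flags, and a stratified two-PSU-per-stratum weighted
# design. Ground truth (onset, wake, wake bouts, duration, efficiency) is
# returned alongside, so the whole pipeline can be validated by recovery.

.age_s <- function(age) (age - 45) / 40

.quartic <- function(age, coeffs) {
  s <- .age_s(age)
  drop(cbind(1, s, s^2, s^3, s^4) %*% coeffs)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode a population whose age trends qualitatively match what is
#' seen in US national accelerometry: sleep onset latest (about 23.6 on the
#' 12-36 h clock, i.e. 11:36 pm) near age 24, sleep duration minimal (about
#' 7.9 h) near age 40, efficiency drifting down with age; females fall
#' asleep about 4.6 min later and sleep about 4 min longer; NH Black
#' subjects sleep later, shorter and less efficiently, Mexican American
#' subjects earlier. Onset/duration age curves are quartic polynomials in
#' scaled age \eqn{s = (age - 45)/40}.
#'
#' @param n_subjects number of subjects
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed)
#' @param n_days recording days per subject (NHANES protocol: 7)
#' @param age_range integer age range, uniform sampling
#' @param onset_curve_coeffs,duration_curve_coeffs quartic coefficients
#'   (intercept, s, s^2, s^3, s^4) on scaled age; hours (onset on the
#'   12-36 h clock)
#' @param sex_onset_shift,sex_duration_shift additive female shifts, hours
#' @param race_onset_shift,race_duration_shift,race_efficiency_shift named
#'   per-race offsets (reference NH White)
#' @param efficiency_intercept,efficiency_age_slope,efficiency_sd linear
#'   age model for the per-night target sleep efficiency plus night-level
#'   Gaussian jitter
#' @param onset_sd night-to-night SD of sleep onset, hours
#' @param wake_bout_rate expected number of wake bouts per night (Poisson)
#' @param wake_bout_max_len longest single wake bout emitted, minutes; kept
#'   under the SPT merge tolerance so a true sleep period is never split
#' @param emission_sleep,emission_wake (mean, sd) of log(1+MIMS) per state
#' @param nonwear_block_prob per-day probability of a device non-wear block
#' @param nonwear_block_len non-wear block length, minutes
#' @param flag_prob per-minute probability of a positive quality-flag count
#' @param sentinel_prob per-minute probability of the -0.01 invalid-value
#'   sentinel
#' @param unknown_prob per-minute probability of an "unknown" wear
#'   prediction (value still emitted)
#' @param n_strata,psus_per_stratum survey design shape (two PSUs per
#'   stratum, the NHANES public-use structure; 30 strata emulate two
#'   combined 2-year cycles of about 15 masked variance strata each)
#' @param weight_range admissible 2-year exam weights
#' @param weekend_onset_delay,weekend_wake_delay minutes added to onset and
#'   wakeup on nights anchored on a Friday or Saturday noon
#' @return an object of class \code{cohort_config}
#' @export
cohort_config <- function(
    n_subjects = 300L, seed = 1L, n_days = 7L, age_range = c(6L, 85L),
    onset_curve_coeffs = c(22.7437, -1.4986, 2.2248, 1.9453, -3.5615),
    duration_curve_coeffs = c(7.8664, 0.1305, 0.6471, -0.5804, 0.3616),
    sex_onset_shift = 0.076, sex_duration_shift = 4 / 60,
    race_onset_shift = c("NH White" = 0, "NH Black" = 10 / 60,
                         "Mexican American" = -11 / 60, "Other" = 10 / 60),
    race_duration_shift = c("NH White" = 0, "NH Black" = -15 / 60,
                            "Mexican American" = 0, "Other" = -7 / 60),
    race_efficiency_shift = c("NH White" = 0, "NH Black" = -0.010,
                              "Mexican American" = -0.005, "Other" = -0.003),
    efficiency_intercept = 0.983, efficiency_age_slope = -0.00035,
    efficiency_sd = 0.008, onset_sd = 0.75,
    wake_bout_rate = 3, wake_bout_max_len = 45,
    emission_sleep = c(0.4, 0.4), emission_wake = c(2.8, 0.6),
    nonwear_block_prob = 0.08, nonwear_block_len = 120L,
    flag_prob = 0.002, sentinel_prob = 5e-4, unknown_prob = 0.001,
    n_strata = 30L, psus_per_stratum = 2L,
    weight_range = c(4000, 60000),
    weekend_onset_delay = 35, weekend_wake_delay = 70) {
  cfg <- as.list(environment())
  .assert(cfg$n_subjects >= 1 && cfg$n_days >= 1, "need >= 1 subject and day",
          "actisleep_config_error")
  .assert(cfg$psus_per_stratum == 2L,
          "design requires exactly 2 PSUs per stratum",
          "actisleep_config_error")
  .assert(cfg$onset_sd >= 0 && cfg$efficiency_sd >= 0 &&
            cfg$emission_sleep[2] > 0 && cfg$emission_wake[2] > 0,
          "all standard deviations must be positive",
          "actisleep_config_error")
  for (nm in c("race_onset_shift", "race_duration_shift",
               "race_efficiency_shift"))
    .assert(setequal(names(cfg[[nm]]), .RACE_LEVELS),
            sprintf("%s must be named with the 4 race groups", nm),
            "actisleep_config_error")
  # a duration curve leaving (3, 15) h would trip the SPT-length filter
  # systematically rather than at random
  grid <- seq(age_range[1], age_range[2], by = 0.5)
  dmax_shift <- max(abs(cfg$sex_duration_shift), abs(cfg$race_duration_shift))
  d <- .quartic(grid, cfg$duration_curve_coeffs)
  .assert(all(d - dmax_shift > 3) && all(d + dmax_shift < 15),
          "duration curve (plus shifts) must stay within (3, 15) h",
          "actisleep_config_error")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, days: %d, ages %d-%d, seed %d\n",
              x$n_subjects, x$n_days, x$age_range[1], x$age_range[2],
              x$seed))
  cat(sprintf("  emissions log(1+MIMS): sleep N(%.2f, %.2f), wake N(%.2f, %.2f)\n",
              x$emission_sleep[1], x$emission_sleep[2],
              x$emission_wake[1], x$emission_wake[2]))
  cat(sprintf("  design: %d strata x %d PSUs\n", x$n_strata,
              x$psus_per_stratum))
  invisible(x)
}

# demographics + survey design ---------------------------------------------

.sim_demographics <- function(cfg) {
  n <- cfg$n_subjects
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  sex <- sample(.SEX_LEVELS, n, replace = TRUE)
  race_p <- c(0.6444, 0.1148, 0.1010, 0.1397)
  race <- sample(.RACE_LEVELS, n, replace = TRUE, prob = race_p / sum(race_p))
  # strata assigned in shuffled round-robin, PSUs alternating within each
  # stratum, so every stratum keeps >= 2 PSUs (Taylor linearization needs
  # between-PSU contrasts everywhere)
  stratum <- sample(rep_len(seq_len(cfg$n_strata), n))
  psu <- integer(n)
  for (h in unique(stratum)) {
    idx <- which(stratum == h)
    psu[idx] <- rep_len(seq_len(cfg$psus_per_stratum), length(idx))
  }
  # weights inverse to an age-band sampling rate: children and the elderly
  # oversampled, hence down-weighted
  band <- .age_group(age)
  rate <- c(2, 2, 1, 1, 1, 1, 1, 1.5, 1.5)[as.integer(band)]
  w <- mean(cfg$weight_range) / 2 / rate * runif(n, 0.8, 1.25)
  w <- pmin(pmax(w, cfg$weight_range[1]), cfg$weight_range[2])
  data.frame(subject_id = sprintf("S%04d", seq_len(n)), age_years = age,
             sex = sex, race = race, weight_2yr = w, stratum = stratum,
             psu = psu, cycle = sample(c("A", "B"), n, replace = TRUE),
             start_dow = sample(1:7, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# true nightly schedules ----------------------------------------------------

.sim_truth <- function(cfg, demo) {
  n <- nrow(demo)
  grid <- expand.grid(i = seq_len(n), day_index = seq_len(cfg$n_days))
  i <- grid$i; d <- grid$day_index
  age <- demo$age_years[i]
  female <- demo$sex[i] == "female"
  race <- demo$race[i]
  anchor_dow <- ((demo$start_dow[i] - 1 + d - 1) %% 7) + 1
  weekend <- anchor_dow %in% c(6L, 7L)  # Friday or Saturday anchored noon

  onset_mean <- .quartic(age, cfg$onset_curve_coeffs) +
    cfg$sex_onset_shift * female + cfg$race_onset_shift[race] +
    weekend * cfg$weekend_onset_delay / 60
  onset <- pmin(pmax(rnorm(length(i), onset_mean, cfg$onset_sd), 13), 33)

  dur_target <- .quartic(age, cfg$duration_curve_coeffs) +
    cfg$sex_duration_shift * female + cfg$race_duration_shift[race]
  eff_target <- pmin(pmax(
    cfg$efficiency_intercept + cfg$efficiency_age_slope * age +
      cfg$race_efficiency_shift[race] +
      rnorm(length(i), 0, cfg$efficiency_sd), 0.86), 0.995)

  spt <- dur_target / eff_target
  wake <- onset + spt +
    weekend * (cfg$weekend_wake_delay - cfg$weekend_onset_delay) / 60

  onset_min <- round(onset * 60)
  wake_min <- round(wake * 60)
  spt_min <- wake_min - onset_min

  k <- rpois(length(i), cfg$wake_bout_rate)
  B <- ifelse(k > 0, round(spt_min * (1 - eff_target)), 0L)
  # keep each bout under the merge gap: a single true sleep period must not
  # be split into two candidate blocks by its own bouts
  k <- pmax(k, ceiling(B / cfg$wake_bout_max_len))
  k <- pmin(k, pmax(B, 0L))
  B[k == 0] <- 0L

  bouts <- character(length(i))
  for (r in seq_along(i)) {
    if (k[r] == 0) next
    len <- rep(B[r] %/% k[r], k[r])
    extra <- B[r] - sum(len)
    if (extra > 0) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
    # sleep gaps around the bouts: k+1 gaps, each >= 1 minute
    S <- spt_min[r] - B[r]
    g <- as.vector(rmultinom(1, S - (k[r] + 1), rep(1, k[r] + 1))) + 1L
    starts <- cumsum(g[seq_len(k[r])]) + c(0L, cumsum(len))[seq_len(k[r])]
    bouts[r] <- paste(starts, len, sep = ":", collapse = ";")
  }

  true_onset <- onset_min / 60
  true_wake <- wake_min / 60
  true_duration <- (spt_min - B) / 60
  data.frame(subject_id = demo$subject_id[i], day_index = d,
             anchor_dow = anchor_dow, is_weekend = weekend,
             true_onset = true_onset, true_wake = true_wake,
             true_spt_h = spt_min / 60, true_n_bouts = k,
             true_bout_min = B, true_bouts = bouts,
             true_duration = true_duration,
             true_efficiency = (spt_min - B) / spt_min,
             stringsAsFactors = FALSE)
}

.parse_bouts <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(0), ncol = 2))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) as.integer(p)))
}

# minute-level emissions ----------------------------------------------------

.sim_minutes_one <- function(cfg, truth_i, start_dow) {
  T <- cfg$n_days * 1440L
  sleep <- logical(T)
  for (r in seq_len(nrow(truth_i))) {
    a <- (truth_i$day_index[r] - 1L) * 1440L +
      as.integer(round(truth_i$true_onset[r] * 60))
    b <- (truth_i$day_index[r] - 1L) * 1440L +
      as.integer(round(truth_i$true_wake[r] * 60))
    lo <- max(a, 0L); hi <- min(b, T)
    if (lo < hi) sleep[(lo + 1L):hi] <- TRUE
    bm <- .parse_bouts(truth_i$true_bouts[r])
    if (nrow(bm)) for (q in seq_len(nrow(bm))) {
      s <- a + bm[q, 1]; e <- s + bm[q, 2]
      s <- max(s, 0L); e <- min(e, T)
      if (s < e) sleep[(s + 1L):e] <- FALSE
    }
  }
  mu <- ifelse(sleep, cfg$emission_sleep[1], cfg$emission_wake[1])
  sdv <- ifelse(sleep, cfg$emission_sleep[2], cfg$emission_wake[2])
  x <- pmax(expm1(rnorm(T, mu, sdv)), 0)
  wear <- ifelse(sleep, "sleep-wear", "wake-wear")

  # device-off blocks: what preprocessing must find and impute
  for (dd in seq_len(cfg$n_days)) {
    if (runif(1) < cfg$nonwear_block_prob) {
      s <- (dd - 1L) * 1440L +
        sample.int(1440L - cfg$nonwear_block_len, 1L)
      idx <- s:(s + cfg$nonwear_block_len - 1L)
      wear[idx] <- "non-wear"
      x[idx] <- 0
    }
  }
  unk <- runif(T) < cfg$unknown_prob
  wear[unk & wear != "non-wear"] <- "unknown"
  sent <- runif(T) < cfg$sentinel_prob
  x[sent] <- -0.01
  qf <- ifelse(runif(T) < cfg$flag_prob, 1L, 0L)

  day_index <- rep(seq_len(cfg$n_days), each = 1440L)
  data.frame(day_index = day_index,
             minute_of_day = rep(0:1439, cfg$n_days),
             calendar_dow = ((start_dow - 1 + day_index - 1) %% 7) + 1,
             mims_triaxial = x, wear_pred = wear, quality_flag_count = qf,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic accelerometer cohort
#'
#' Draws demographics and survey design, nightly true sleep schedules from
#' the age/sex/race curves, and (optionally) the minute-level MIMS table
#' with log-normal state-dependent emissions, non-wear blocks, quality
#' flags and \code{-0.01} sentinels.
#'
#' @param config a \code{\link{cohort_config}}
#' @param minutes if \code{FALSE}, skip minute-level emission (fast path for
#'   design/regression simulations that only need subject-level truth)
#' @return list with data.frames \code{demographics}, \code{truth} (one row
#'   per subject-night) and, when \code{minutes = TRUE}, \code{minutes}
#'   (one row per subject-minute)
#' @export
simulate_cohort <- function(config = cohort_config(), minutes = TRUE) {
  .assert(inherits(config, "cohort_config"), "config must be a cohort_config",
          "actisleep_config_error")
  set.seed(config$seed)
  demo <- .sim_demographics(config)
  truth <- .sim_truth(config, demo)
  truth <- truth[order(truth$subject_id, truth$day_index), ]
  rownames(truth) <- NULL
  out <- list(demographics = demo, truth = truth)
  if (minutes) {
    per <- vector("list", nrow(demo))
    for (s in seq_len(nrow(demo))) {
      m <- .sim_minutes_one(config,
                            truth[truth$subject_id == demo$subject_id[s], ],
                            demo$start_dow[s])
      m$subject_id <- demo$subject_id[s]
      per[[s]] <- m
    }
    mins <- do.call(rbind, per)
    out$minutes <- mins[c("subject_id", "day_index", "minute_of_day",
                          "calendar_dow", "mims_triaxial", "wear_pred",
                          "quality_flag_count")]
    rownames(out$minutes) <- NULL
  }
  out$config <- config
  class(out) <- "cohort_sim"
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d nights%s\n",
              nrow(x$demographics), nrow(x$truth),
              if (!is.null(x$minutes))
                sprintf(", %d subject-minutes", nrow(x$minutes)) else ""))
  invisible(x)
}

#' Per-subject means of the true nightly sleep parameters
#'
#' @param truth the \code{truth} table from \code{\link{simulate_cohort}}
#' @return data.frame with one row per subject: mean true onset, duration
#'   and efficiency, and the night count
#' @export
truth_summary <- function(truth) {
  .assert(nrow(truth) > 0, "truth table is empty", "actisleep_error")
  agg <- aggregate(truth[c("true_onset", "true_duration",
                           "true_efficiency")],
                   by = list(subject_id = truth$subject_id), FUN = mean)
  agg$n_nights <- as.vector(table(truth$subject_id)[agg$subject_id])
  agg
}
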