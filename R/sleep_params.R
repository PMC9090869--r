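# Nightly sleep parameters from per-minute sleep/wake labels.
#
# The analysis unit is the noon-to-noon "sleep day": within each window the
# longest merged block of sleep is the sleep period time (SPT) window, its
# start is the clock time of sleep onset (CTSO, on a continuous 12-36 h
# clock where 1 am = 25), wake runs strictly inside it are wake bouts, and
#   sleep duration   = SPT duration - summed wake-bout duration
#   sleep efficiency = sleep duration / SPT duration.
# Nights with SPT < 3 h or > 15 h are invalid; subjects need >= 3 valid
# nights.

#' Assign minutes to noon-to-noon windows
#'
#' Window \code{w >= 1} covers minutes \code{[noon of day w, noon of day
#' w+1)}; minutes before the first noon fall in partial window 0. A window
#' with fewer than 1440 recorded minutes is flagged partial.
#'
#' @param decoded data.frame with columns \code{subject_id},
#'   \code{day_index}, \code{minute_of_day}, \code{calendar_dow} and a
#'   per-minute label column (e.g. \code{sleep})
#' @return the input with added columns \code{window} (integer id) and
#'   \code{offset} (minutes from the window's anchor noon, 0..1439)
#' @export
split_noon_days <- function(decoded) {
  abs_min <- (decoded$day_index - 1L) * 1440L + decoded$minute_of_day
  w <- ifelse(abs_min < 720L, 0L, (abs_min - 720L) %/% 1440L + 1L)
  decoded$window <- w
  decoded$offset <- abs_min - 720L - (w - 1L) * 1440L
  decoded
}

#' Find the sleep period time (SPT) window in one labeled noon-window
#'
#' Sleep runs separated by wake runs shorter than \code{merge_gap_max} are
#' merged into candidate blocks; the longest block (ties: earliest start)
#' is the SPT window. Blocks start and end in sleep by construction, so no
#' wake bout touches the SPT boundary.
#'
#' @param sleep logical vector of per-minute labels, ordered by offset
#' @param merge_gap_max wake runs of at least this many minutes split
#'   blocks; shorter ones become internal wake bouts (default 60)
#' @return integer \code{c(start, end)} as 0-based half-open offsets into
#'   \code{sleep}, or \code{NULL} if the window contains no sleep
#' @export
find_spt_window <- function(sleep, merge_gap_max = 60L) {
  if (!any(sleep)) return(NULL)
  r <- .runs(sleep)
  sl <- which(r$value)
  # chain sleep runs whose separating wake run is < merge_gap_max
  block_id <- cumsum(c(1L, vapply(seq_along(sl)[-1], function(j) {
    gap <- r$start[sl[j]] - (r$start[sl[j - 1]] + r$length[sl[j - 1]])
    as.integer(gap >= merge_gap_max)
  }, integer(1))))
  best_len <- -1L; best <- NULL
  for (b in unique(block_id)) {
    runs_b <- sl[block_id == b]
    s <- r$start[runs_b[1]] - 1L                       # 0-based
    e <- r$start[runs_b[length(runs_b)]] +
      r$length[runs_b[length(runs_b)]] - 1L
    if ((e - s) > best_len) { best_len <- e - s; best <- c(s, e) }
  }
  best
}

#' Clock time of sleep onset on the continuous 12-36 h scale
#'
#' Maps minutes after the anchor noon to clock hours so that times past
#' midnight stay on a linear scale: 11 pm maps to 23, midnight to 24, 1 am
#' to 25.
#'
#' @param spt_start_min minutes from the anchor noon (0..1439)
#' @return clock hours in [12, 36)
#' @export
onset_clock_transform <- function(spt_start_min) {
  .assert(all(spt_start_min >= 0 & spt_start_min < 1440),
          "spt_start_min must lie in [0, 1440)", "actisleep_error")
  12 + spt_start_min / 60
}

#' Wake bouts inside an SPT window
#'
#' Maximal runs of wake strictly inside \code{[spt[1], spt[2])}. Because
#' the SPT window is built by merging, every bout is shorter than the merge
#' gap and none touches the boundary.
#'
#' @inheritParams find_spt_window
#' @param spt 0-based half-open \code{c(start, end)} from
#'   \code{\link{find_spt_window}}
#' @return data.frame with columns \code{start} (0-based offset within the
#'   window) and \code{length} (minutes); zero rows if sleep is unbroken
#' @export
wake_bouts <- function(sleep, spt) {
  seg <- sleep[(spt[1] + 1L):spt[2]]
  r <- .runs(!seg)
  r <- r[r$value, c("start", "length")]
  r$start <- r$start - 1L + spt[1]
  rownames(r) <- NULL
  r
}

#' Nightly sleep parameters from an SPT window and its wake bouts
#'
#' @param spt 0-based half-open \code{c(start, end)} offsets from the
#'   anchor noon
#' @param bouts data.frame from \code{\link{wake_bouts}}
#' @param spt_bounds valid SPT duration range in hours (default 3-15;
#'   nights outside it are flagged invalid)
#' @return one-row data.frame: \code{spt_start_min}, \code{spt_end_min},
#'   \code{onset_clock}, \code{wakeup_clock}, \code{n_bouts},
#'   \code{bout_min}, \code{spt_len_h}, \code{sleep_duration_h},
#'   \code{sleep_efficiency}, \code{valid}
#' @export
night_parameters <- function(spt, bouts, spt_bounds = c(3, 15)) {
  .assert(spt[2] > spt[1], "zero-length SPT window", "actisleep_error")
  spt_len_h <- (spt[2] - spt[1]) / 60
  bout_min <- sum(bouts$length)
  dur <- spt_len_h - bout_min / 60
  data.frame(spt_start_min = spt[1], spt_end_min = spt[2],
             onset_clock = onset_clock_transform(spt[1]),
             wakeup_clock = 12 + spt[2] / 60,
             n_bouts = nrow(bouts), bout_min = bout_min,
             spt_len_h = spt_len_h, sleep_duration_h = dur,
             sleep_efficiency = dur / spt_len_h,
             valid = spt_len_h >= spt_bounds[1] & spt_len_h <= spt_bounds[2])
}

#' Weekend-night classification
#'
#' A night is a weekend night iff its anchor noon falls on a Friday or a
#' Saturday (day-of-week coding 1 = Sunday), i.e. the sleep episode
#' precedes a school/work-free morning.
#'
#' @param anchor_dow day of week (1-7, 1 = Sunday) of the window's anchor
#'   noon
#' @return logical
#' @export
weekend_classification <- function(anchor_dow) {
  anchor_dow %in% c(6L, 7L)
}

#' Score all nights of all subjects
#'
#' Splits each subject's decoded series into noon-to-noon windows, finds
#' the SPT window in each, and derives the nightly parameters. A night in a
#' partially recorded window is only valid when its SPT lies strictly
#' inside the recorded region (a truncated SPT must not masquerade as
#' short sleep); windows without sleep yield an invalid night with NA
#' parameters.
#'
#' @param decoded data.frame with columns \code{subject_id},
#'   \code{day_index}, \code{minute_of_day}, \code{calendar_dow},
#'   \code{sleep}
#' @param merge_gap_max SPT merge tolerance, minutes
#' @param spt_bounds valid SPT range, hours
#' @return one row per subject-window night table; see
#'   \code{\link{night_parameters}} plus \code{sleep_day_index},
#'   \code{is_weekend_night}, \code{partial_window}
#' @export
score_nights <- function(decoded, merge_gap_max = 60L,
                         spt_bounds = c(3, 15)) {
  dd <- split_noon_days(decoded)
  dd <- dd[order(dd$subject_id, dd$window, dd$offset), ]
  out <- list()
  for (sid in unique(dd$subject_id)) {
    ds <- dd[dd$subject_id == sid, ]
    for (w in unique(ds$window)) {
      dw <- ds[ds$window == w, ]
      partial <- nrow(dw) < 1440L
      # anchor dow: dow of the day containing the anchor noon
      anchor_dow <- if (w >= 1 && any(dw$offset < 720)) {
        dw$calendar_dow[which.min(dw$offset)]
      } else {
        # window 0 (or a late-start window): anchor day precedes the first
        # recorded day
        ((dw$calendar_dow[which.min(dw$offset)] - 1 - 1) %% 7) + 1
      }
      base <- data.frame(subject_id = sid, sleep_day_index = w,
                         is_weekend_night = weekend_classification(anchor_dow),
                         partial_window = partial,
                         stringsAsFactors = FALSE)
      spt_local <- find_spt_window(dw$sleep, merge_gap_max)
      if (is.null(spt_local)) {
        np <- data.frame(spt_start_min = NA_integer_,
                         spt_end_min = NA_integer_, onset_clock = NA_real_,
                         wakeup_clock = NA_real_, n_bouts = NA_integer_,
                         bout_min = NA_integer_, spt_len_h = NA_real_,
                         sleep_duration_h = NA_real_,
                         sleep_efficiency = NA_real_, valid = FALSE)
      } else {
        # offsets within the recorded part -> offsets from the anchor noon
        off0 <- dw$offset[1]
        spt <- spt_local + off0
        bouts <- wake_bouts(dw$sleep, spt_local)
        bouts$start <- bouts$start + off0
        np <- night_parameters(spt, bouts, spt_bounds)
        if (partial &&
            (spt_local[1] == 0L || spt_local[2] == nrow(dw)))
          np$valid <- FALSE   # SPT truncated by the recording edge
      }
      out[[length(out) + 1L]] <- cbind(base, np)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject sleep summaries
#'
#' Unweighted means over valid nights; a subject is included only with at
#' least \code{min_valid_nights} valid nights. Weekday/weekend sub-means
#' are reported only when the corresponding side has at least one valid
#' night (otherwise NA, never zero).
#'
#' @param nights night table from \code{\link{score_nights}}
#' @param min_valid_nights inclusion threshold (default 3)
#' @return one row per subject: \code{n_valid_nights},
#'   \code{mean_onset_clock}, \code{mean_duration_h},
#'   \code{mean_efficiency}, \code{mean_onset_weekday},
#'   \code{mean_onset_weekend}, \code{mean_wakeup_weekday},
#'   \code{mean_wakeup_weekend}, \code{included}
#' @export
aggregate_subjects <- function(nights, min_valid_nights = 3L) {
  out <- lapply(split(nights, nights$subject_id), function(ns) {
    v <- ns[ns$valid, ]
    sub <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_
    data.frame(subject_id = ns$subject_id[1],
               n_valid_nights = nrow(v),
               mean_onset_clock = if (nrow(v)) mean(v$onset_clock) else NA_real_,
               mean_duration_h = if (nrow(v)) mean(v$sleep_duration_h) else NA_real_,
               mean_efficiency = if (nrow(v)) mean(v$sleep_efficiency) else NA_real_,
               mean_onset_weekday = sub(v$onset_clock, !v$is_weekend_night),
               mean_onset_weekend = sub(v$onset_clock, v$is_weekend_night),
               mean_wakeup_weekday = sub(v$wakeup_clock, !v$is_weekend_night),
               mean_wakeup_weekend = sub(v$wakeup_clock, v$is_weekend_night),
               included = nrow(v) >= min_valid_nights,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
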