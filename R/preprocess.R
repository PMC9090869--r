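# Minute-level quality masking, wear-day validity, subject eligibility and
# imputation of long missing intervals.
#
# Rules (NHANES-style minute summaries):
#   * a minute is missing iff MIMS = -0.01, wear prediction = non-wear, or
#     quality-flag count > 0;
#   * only maximal missing runs of >= 60 min are imputable intervals;
#     shorter missing runs contribute a value of 0;
#   * a valid wear day has > 16 h (strictly > 960 min) of wear, where wear
#     is what the wear-prediction flag says (the flag, not the value,
#     encodes wear; "unknown" counts as wear);
#   * subjects need >= 4 valid days to be imputed and scored.

#' Mask invalid minutes
#'
#' Marks a minute missing iff its MIMS value is the \code{-0.01} sentinel,
#' its wear prediction is \code{"non-wear"}, or its quality-flag count is
#' positive. All other minutes are untouched. Idempotent.
#'
#' @param minutes a minute table as returned by
#'   \code{\link{read_minute_table}} (or the \code{minutes} element of a
#'   \code{\link{simulate_cohort}} result)
#' @return data.frame ordered by (subject, day, minute) with columns
#'   \code{subject_id}, \code{day_index}, \code{minute_of_day},
#'   \code{calendar_dow}, \code{value} (NA where missing), \code{missing},
#'   \code{wear}
#' @export
mask_invalid_minutes <- function(minutes) {
  need <- c("subject_id", "day_index", "minute_of_day", "mims_triaxial",
            "wear_pred", "quality_flag_count")
  .assert(all(need %in% names(minutes)),
          paste("minute table lacks columns:",
                paste(setdiff(need, names(minutes)), collapse = ", ")),
          "actisleep_schema_error")
  o <- order(minutes$subject_id, minutes$day_index, minutes$minute_of_day)
  minutes <- minutes[o, ]
  miss <- minutes$mims_triaxial == -0.01 |
    minutes$wear_pred == "non-wear" | minutes$quality_flag_count > 0
  val <- ifelse(miss, NA_real_, minutes$mims_triaxial)
  data.frame(subject_id = minutes$subject_id,
             day_index = minutes$day_index,
             minute_of_day = minutes$minute_of_day,
             calendar_dow = minutes$calendar_dow %||%
               rep(NA_integer_, nrow(minutes)),
             value = val, missing = miss,
             wear = minutes$wear_pred != "non-wear",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Maximal missing intervals of at least a minimum length
#'
#' Scans each subject's concatenated minute series (day boundaries are
#' contiguous in time) for maximal runs of missing minutes and keeps those
#' of length \code{>= min_len}. Shorter missing runs are not imputable;
#' they later contribute a value of 0.
#'
#' @param series output of \code{\link{mask_invalid_minutes}}
#' @param min_len minimum interval length in minutes (default 60)
#' @return data.frame with columns \code{subject_id}, \code{start} (1-based
#'   index into the subject's ordered series), \code{length}
#' @export
missing_intervals <- function(series, min_len = 60L) {
  out <- lapply(split(series$missing, series$subject_id), function(m) {
    r <- .runs(m)
    r <- r[r$value & r$length >= min_len, c("start", "length")]
    r
  })
  ns <- vapply(out, nrow, integer(1))
  data.frame(subject_id = rep(names(out), ns),
             do.call(rbind, out), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag valid wear days
#'
#' A day is valid iff it has strictly more than \code{min_wear_min} minutes
#' of wear (default 960 = 16 h), wear being what the device's wear
#' prediction asserts.
#'
#' @inheritParams missing_intervals
#' @param min_wear_min strict lower bound on daily wear minutes
#' @return data.frame with columns \code{subject_id}, \code{day_index},
#'   \code{wear_min}, \code{valid_day}
#' @export
flag_valid_days <- function(series, min_wear_min = 960L) {
  agg <- aggregate(list(wear_min = as.integer(series$wear)),
                   by = list(subject_id = series$subject_id,
                             day_index = series$day_index), FUN = sum)
  agg <- agg[order(agg$subject_id, agg$day_index), ]
  agg$valid_day <- agg$wear_min > min_wear_min
  rownames(agg) <- NULL
  agg
}

#' Subject-level imputation eligibility
#'
#' A subject is eligible for imputation (and hence for sleep scoring) iff
#' they have at least \code{min_valid_days} valid wear days.
#'
#' @param valid_days output of \code{\link{flag_valid_days}}
#' @param min_valid_days minimum number of valid days (default 4)
#' @return data.frame with columns \code{subject_id}, \code{n_valid_days},
#'   \code{eligible}
#' @export
imputation_eligibility <- function(valid_days, min_valid_days = 4L) {
  agg <- aggregate(list(n_valid_days = as.integer(valid_days$valid_day)),
                   by = list(subject_id = valid_days$subject_id), FUN = sum)
  agg$eligible <- agg$n_valid_days >= min_valid_days
  agg
}

# donor lookup for one subject: mean (or draws) by minute-of-day on valid
# days, with day-level then subject-level fallback
.impute_one <- function(val, miss, mod, day, valid_day_ids, target_idx,
                        method) {
  donor_ok <- !miss & day %in% valid_day_ids
  fellback <- FALSE
  prof_mean <- tapply(val[donor_ok], mod[donor_ok], mean)
  out <- numeric(length(target_idx))
  for (j in seq_along(target_idx)) {
    t <- target_idx[j]
    key <- as.character(mod[t])
    donors <- val[donor_ok & mod == mod[t]]
    if (!length(donors)) {
      # no donor at this minute-of-day on any valid day: day-level mean
      fellback <- TRUE
      donors <- val[!miss & day == day[t]]
      if (!length(donors)) donors <- val[!miss]
    }
    if (method == "minute_profile") {
      out[j] <- mean(donors)
    } else { # zip_model: zero-inflation + log-normal positive part
      p0 <- mean(donors < 0.01)
      pos <- donors[donors >= 0.01]
      if (runif(1) < p0 || !length(pos)) {
        out[j] <- 0
      } else if (length(pos) == 1) {
        out[j] <- pos
      } else {
        lp <- log(pos)
        out[j] <- rlnorm(1, mean(lp), max(sd(lp), 1e-6))
      }
    }
  }
  list(values = out, fellback = fellback)
}

#' Impute missing activity values
#'
#' Minutes inside qualifying missing intervals (maximal missing runs of
#' \code{>= min_len} minutes) are replaced; sub-threshold missing runs are
#' set to 0. Two methods:
#' \describe{
#'   \item{\code{minute_profile}}{the subject's mean non-missing value at
#'     the same minute-of-day across their valid days (deterministic,
#'     default);}
#'   \item{\code{zip_model}}{a seeded draw from a zero-inflated model of
#'     the subject's minute-of-day profile: with the donor zero-fraction
#'     emit 0, otherwise a log-normal draw fit to the positive donors.}
#' }
#' If a minute-of-day has no donors on any valid day, the day-level mean is
#' used and the subject is listed in the \code{fallback_subjects}
#' attribute.
#'
#' @inheritParams missing_intervals
#' @param valid_days output of \code{\link{flag_valid_days}} (computed if
#'   missing)
#' @param method \code{"minute_profile"} or \code{"zip_model"}
#' @param seed seed for \code{zip_model} draws
#' @return the series with \code{value} filled everywhere (no NA left) and
#'   a logical \code{imputed} column marking interval-imputed minutes
#' @export
impute_missing <- function(series, valid_days = NULL,
                           method = c("minute_profile", "zip_model"),
                           min_len = 60L, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(valid_days)) valid_days <- flag_valid_days(series)
  series <- series[order(series$subject_id, series$day_index,
                         series$minute_of_day), ]
  rownames(series) <- NULL
  series$imputed <- FALSE
  fallback <- character(0)
  for (sid in unique(series$subject_id)) {
    idx <- which(series$subject_id == sid)
    miss <- series$missing[idx]
    if (!any(miss)) next
    r <- .runs(miss)
    long <- r$value & r$length >= min_len
    imp_local <- unlist(lapply(which(long), function(k)
      seq(r$start[k], length.out = r$length[k])), use.names = FALSE)
    zero_local <- setdiff(which(miss), imp_local)
    if (length(zero_local)) series$value[idx[zero_local]] <- 0
    if (length(imp_local)) {
      vids <- valid_days$day_index[valid_days$subject_id == sid &
                                     valid_days$valid_day]
      res <- .impute_one(series$value[idx], miss,
                         series$minute_of_day[idx], series$day_index[idx],
                         vids, imp_local, method)
      series$value[idx[imp_local]] <- res$values
      series$imputed[idx[imp_local]] <- TRUE
      if (res$fellback) fallback <- c(fallback, sid)
    }
  }
  attr(series, "fallback_subjects") <- fallback
  series
}

#' One-call preprocessing
#'
#' Masking, valid-day flags, eligibility, and imputation, with a per-day QC
#' table. Ineligible subjects (< \code{min_valid_days} valid days) are
#' dropped from the returned series.
#'
#' @param minutes a minute table
#' @inheritParams impute_missing
#' @inheritParams flag_valid_days
#' @inheritParams imputation_eligibility
#' @return list with \code{series} (imputed, eligible subjects only),
#'   \code{valid_days}, \code{eligibility}, \code{qc}
#' @export
preprocess_minutes <- function(minutes, method = "minute_profile",
                               min_len = 60L, min_wear_min = 960L,
                               min_valid_days = 4L, seed = NULL) {
  clean <- mask_invalid_minutes(minutes)
  vd <- flag_valid_days(clean, min_wear_min)
  elig <- imputation_eligibility(vd, min_valid_days)
  ivals <- missing_intervals(clean, min_len)
  qc_miss <- aggregate(list(n_missing = as.integer(clean$missing)),
                       by = list(subject_id = clean$subject_id,
                                 day_index = clean$day_index), FUN = sum)
  qc <- merge(vd, qc_miss, by = c("subject_id", "day_index"))
  keep <- elig$subject_id[elig$eligible]
  series <- clean[clean$subject_id %in% keep, ]
  series <- impute_missing(series, vd, method, min_len, seed)
  list(series = series, valid_days = vd, eligibility = elig,
       intervals = ivals, qc = qc)
}
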