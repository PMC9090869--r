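# End-to-end orchestration: simulate/load -> preprocess -> HMM scoring ->
# nightly sleep parameters -> design-based analysis, with an attrition
# manifest mirroring the usual inclusion flowchart.

#' Per-subject HMM fitting and decoding
#'
#' Fits one unsupervised two-state HMM per subject on their concatenated
#' (imputed) multi-day series and decodes per-minute sleep/wake labels.
#' Subjects with a degenerate (constant-series) fit are skipped.
#'
#' @param series imputed series from \code{\link{preprocess_minutes}} (or
#'   \code{\link{impute_missing}})
#' @param rule decoding rule, \code{"posterior"} or \code{"viterbi"}
#' @param init,tol,max_iter,seed passed to \code{\link{sleep_hmm}}
#' @return list: \code{decoded} (the series with \code{sleep} and
#'   \code{post_sleep} columns), \code{models} (named list of
#'   \code{sleep_hmm} fits), \code{skipped} (degenerate subject ids)
#' @export
score_sleep <- function(series, rule = c("posterior", "viterbi"),
                        init = "quantile_split", tol = 1e-6,
                        max_iter = 200L, seed = NULL) {
  rule <- match.arg(rule)
  series <- series[order(series$subject_id, series$day_index,
                         series$minute_of_day), ]
  models <- list()
  skipped <- character(0)
  parts <- split(seq_len(nrow(series)), series$subject_id)
  series$sleep <- NA
  series$post_sleep <- NA_real_
  for (sid in names(parts)) {
    idx <- parts[[sid]]
    y <- transform_counts(series$value[idx])
    fit <- sleep_hmm(y, init = init, tol = tol, max_iter = max_iter,
                     seed = seed)
    models[[sid]] <- fit
    if (isTRUE(fit$degenerate)) {
      skipped <- c(skipped, sid)
      next
    }
    dec <- decode(fit, y, rule)
    series$sleep[idx] <- dec$sleep
    series$post_sleep[idx] <- dec$post_sleep
  }
  decoded <- series[!series$subject_id %in% skipped, ]
  list(decoded = decoded, models = models, skipped = skipped)
}

#' Pipeline configuration
#'
#' Bundles every stage's tunables; the defaults are the standard thresholds
#' of this analysis (60-min minimum missing interval, > 16 h wear days,
#' >= 4 valid days for imputation, 60-min SPT merge gap, 3-15 h SPT
#' bounds, >= 3 valid nights, quartic age trends, 0.05 significance).
#'
#' @param cohort a \code{\link{cohort_config}} for simulated input
#' @param impute_method \code{"minute_profile"} or \code{"zip_model"}
#' @param min_missing_interval,min_wear_min,min_valid_days preprocessing
#'   thresholds
#' @param hmm_init,hmm_tol,hmm_max_iter,decode_rule HMM settings
#' @param merge_gap_max,spt_bounds,min_valid_nights SPT settings
#' @param interactions interaction blocks for the trend models
#' @param seed root seed; stage seeds are derived from it
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            impute_method = "minute_profile",
                            min_missing_interval = 60L,
                            min_wear_min = 960L, min_valid_days = 4L,
                            hmm_init = "quantile_split", hmm_tol = 1e-6,
                            hmm_max_iter = 200L,
                            decode_rule = "posterior",
                            merge_gap_max = 60L, spt_bounds = c(3, 15),
                            min_valid_nights = 3L,
                            interactions = c("sex", "race"),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates (or takes) a cohort, preprocesses, scores sleep/wake with the
#' per-subject HMM, derives nightly and per-subject sleep parameters,
#' builds the 4-year-weight survey design on the included subjects, and
#' runs the design-based analyses. A manifest records subject counts at
#' every filter stage.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param cohort optional pre-built cohort (list with \code{minutes},
#'   \code{demographics}, optionally \code{truth}); simulated from
#'   \code{config$cohort} when NULL
#' @param out_dir optional directory; when given, result tables are written
#'   there via \code{\link{write_outputs}}
#' @param keep_decoded retain the per-minute decoded series in the result
#'   (large; off by default)
#' @return list of class \code{sleep_pipeline}: \code{nights},
#'   \code{subjects}, \code{analysis} (per-subject analysis table),
#'   \code{design}, \code{population}, \code{quantiles}, \code{trends},
#'   \code{ordinal_efficiency}, \code{models}, \code{manifest}
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL, keep_decoded = FALSE) {
  if (is.null(cohort)) {
    cfg <- config$cohort
    cfg$seed <- config$seed
    cohort <- simulate_cohort(cfg)
  }
  manifest <- list(seed = config$seed,
                   n_subjects_input = length(unique(cohort$minutes$subject_id)))

  prep <- preprocess_minutes(cohort$minutes, method = config$impute_method,
                             min_len = config$min_missing_interval,
                             min_wear_min = config$min_wear_min,
                             min_valid_days = config$min_valid_days,
                             seed = config$seed + 1L)
  manifest$n_imputation_eligible <- sum(prep$eligibility$eligible)

  scored <- score_sleep(prep$series, rule = config$decode_rule,
                        init = config$hmm_init, tol = config$hmm_tol,
                        max_iter = config$hmm_max_iter,
                        seed = config$seed + 2L)
  manifest$n_hmm_scored <- manifest$n_imputation_eligible -
    length(scored$skipped)

  nights <- score_nights(scored$decoded,
                         merge_gap_max = config$merge_gap_max,
                         spt_bounds = config$spt_bounds)
  subjects <- aggregate_subjects(nights, config$min_valid_nights)
  manifest$n_min_valid_nights <- sum(subjects$included)

  demo <- cohort$demographics
  analysis <- merge(subjects[subjects$included, ], demo, by = "subject_id")
  analysis <- analysis[analysis$age_years >= 6, ]
  manifest$n_included <- nrow(analysis)
  analysis <- four_year_weights(analysis, single_cycle = "keep")
  design <- svy_design(analysis$stratum, analysis$psu, analysis$weight_4yr)

  population <- population_summary(analysis, design)
  quantiles <- quantile_table(analysis, design)
  trends <- lapply(setNames(nm = c("mean_onset_clock", "mean_duration_h",
                                   "mean_efficiency")),
                   function(oc) sleep_trend(oc, analysis, design,
                                            interactions = config$interactions))
  # on very small samples the quartile cells can be too sparse for a
  # proportional-odds fit; the stage failure is recorded, not fatal
  ordinal <- tryCatch(efficiency_quartile_ordinal(analysis, design),
                      error = function(e)
                        list(error = conditionMessage(e)))

  out <- list(nights = nights, subjects = subjects, analysis = analysis,
              design = design, population = population,
              quantiles = quantiles, trends = trends,
              ordinal_efficiency = ordinal, models = scored$models,
              qc = prep$qc, manifest = manifest, config = config,
              truth = cohort$truth)
  if (keep_decoded) out$decoded <- scored$decoded
  class(out) <- "sleep_pipeline"
  if (!is.null(out_dir)) {
    curves <- do.call(rbind, lapply(names(trends), function(nm)
      cbind(outcome = nm, trends[[nm]]$curves)))
    write_outputs(list(nights = nights, subjects = subjects,
                       population = population, quantiles = quantiles,
                       fitted_curves = curves), out_dir)
  }
  out
}

#' @export
print.sleep_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Accelerometer sleep pipeline\n")
  cat(sprintf("  input subjects:          %d\n", m$n_subjects_input))
  cat(sprintf("  imputation-eligible:     %d (>= 4 valid wear days)\n",
              m$n_imputation_eligible))
  cat(sprintf("  HMM-scored:              %d\n", m$n_hmm_scored))
  cat(sprintf("  included (>= 3 nights):  %d\n", m$n_included))
  cat("Population estimates (weighted):\n")
  p <- x$population
  for (v in c("mean_duration_h", "mean_onset_clock", "mean_efficiency")) {
    r <- p[p$variable == v, ]
    cat(sprintf("  %-18s %.3f (SE %.3f)\n", v, r$estimate, r$se))
  }
  invisible(x)
}

#' Compare recovered sleep parameters with generator truth
#'
#' Joins the scored night table with the generator's truth on (subject,
#' night) and reports per-subject mean absolute errors for onset (minutes),
#' duration (minutes) and efficiency, averaged over subjects.
#'
#' @param nights night table from \code{\link{score_nights}} (valid nights
#'   are used)
#' @param truth truth table from \code{\link{simulate_cohort}}
#' @return list: \code{per_subject} (data.frame of per-subject MAEs),
#'   \code{mae_onset_min}, \code{mae_duration_min}, \code{mae_efficiency},
#'   \code{n_matched_nights}
#' @export
evaluate_recovery <- function(nights, truth) {
  v <- nights[nights$valid, ]
  j <- merge(v, truth, by.x = c("subject_id", "sleep_day_index"),
             by.y = c("subject_id", "day_index"))
  .assert(nrow(j) > 0, "no matched nights between scored and truth tables",
          "actisleep_error")
  j$err_onset <- abs(j$onset_clock - j$true_onset) * 60
  j$err_dur <- abs(j$sleep_duration_h - j$true_duration) * 60
  j$err_eff <- abs(j$sleep_efficiency - j$true_efficiency)
  per <- aggregate(j[c("err_onset", "err_dur", "err_eff")],
                   by = list(subject_id = j$subject_id), FUN = mean)
  list(per_subject = per,
       mae_onset_min = mean(per$err_onset),
       mae_duration_min = mean(per$err_dur),
       mae_efficiency = mean(per$err_eff),
       n_matched_nights = nrow(j))
}
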