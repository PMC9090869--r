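# Tabular I/O for minute-level activity and demographics tables.
#
# Column names mirror the NHANES minute-summary (PAXMIN) and demographics
# (DEMO) variable names through an alias map, so real NHANES exports load
# without renaming while synthetic tables use readable internal names.

.WEAR_LEVELS <- c("wake-wear", "sleep-wear", "non-wear", "unknown")
.RACE_LEVELS <- c("NH White", "NH Black", "Mexican American", "Other")
.SEX_LEVELS <- c("male", "female")

# internal name = canonical; aliases accepted on read, canonical on write
.MINUTE_ALIASES <- list(
  subject_id        = c("subject_id", "SEQN"),
  day_index         = c("day_index", "PAXDAYM"),
  minute_of_day     = c("minute_of_day", "PAXMINUT"),
  calendar_dow      = c("calendar_dow", "PAXDAYWM"),
  mims_triaxial     = c("mims_triaxial", "PAXMTSM"),
  wear_pred         = c("wear_pred", "PAXPREDM"),
  quality_flag_count = c("quality_flag_count", "PAXQFM")
)

.DEMO_ALIASES <- list(
  subject_id = c("subject_id", "SEQN"),
  age_years  = c("age_years", "RIDAGEYR"),
  sex        = c("sex", "RIAGENDR"),
  race       = c("race", "RIDRETH3"),
  weight_2yr = c("weight_2yr", "WTMEC2YR"),
  stratum    = c("stratum", "SDMVSTRA"),
  psu        = c("psu", "SDMVPSU"),
  cycle      = c("cycle", "SDDSRVYR")
)

.read_table <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "actisleep_io_error")
  if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    .assert(requireNamespace("arrow", quietly = TRUE),
            "parquet support requires the 'arrow' package",
            "actisleep_io_error")
    as.data.frame(arrow::read_parquet(path))
  }
}

.write_table <- function(df, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    .assert(requireNamespace("arrow", quietly = TRUE),
            "parquet support requires the 'arrow' package",
            "actisleep_io_error")
    arrow::write_parquet(df, path)
  }
  invisible(path)
}

.apply_aliases <- function(df, aliases, what) {
  for (canon in names(aliases)) {
    hits <- intersect(aliases[[canon]], names(df))
    .assert(length(hits) > 0,
            sprintf("%s: missing required column '%s' (accepted names: %s)",
                    what, canon, paste(aliases[[canon]], collapse = ", ")),
            "actisleep_schema_error")
    names(df)[names(df) == hits[1]] <- canon
  }
  df[names(aliases)]
}

#' Read a minute-level activity table
#'
#' One row per subject-minute with the triaxial MIMS value, the device's
#' wear/sleep prediction and the quality-flag count. NHANES PAXMIN variable
#' names (SEQN, PAXDAYM, PAXMTSM, PAXPREDM, PAXQFM, PAXDAYWM) are accepted
#' as aliases. The \code{-0.01} MIMS sentinel marking an invalid minute is
#' preserved verbatim; masking happens later in
#' \code{\link{mask_invalid_minutes}}.
#'
#' @param path file path
#' @param format \code{"csv"} or \code{"parquet"}
#' @return data.frame with canonical columns \code{subject_id},
#'   \code{day_index}, \code{minute_of_day}, \code{calendar_dow},
#'   \code{mims_triaxial}, \code{wear_pred} (one of \code{"wake-wear"},
#'   \code{"sleep-wear"}, \code{"non-wear"}, \code{"unknown"}),
#'   \code{quality_flag_count}
#' @export
read_minute_table <- function(path, format = c("csv", "parquet")) {
  df <- .read_table(path, format)
  df <- .apply_aliases(df, .MINUTE_ALIASES, "minute table")
  if (nrow(df) == 0) return(df)
  # numeric wear codes follow the NHANES PAXPREDM coding 1..4
  if (is.numeric(df$wear_pred)) {
    .assert(all(df$wear_pred %in% 1:4),
            "minute table: numeric wear_pred codes must be in 1..4",
            "actisleep_parse_error")
    df$wear_pred <- .WEAR_LEVELS[df$wear_pred]
  }
  bad <- which(!df$wear_pred %in% .WEAR_LEVELS)
  .assert(length(bad) == 0,
          sprintf("minute table: unknown wear_pred value '%s' at row %d",
                  df$wear_pred[bad[1]], bad[1]), "actisleep_parse_error")
  .assert(all(df$mims_triaxial >= 0 | df$mims_triaxial == -0.01),
          "minute table: mims_triaxial must be >= 0 or the sentinel -0.01",
          "actisleep_integrity_error")
  .assert(all(df$quality_flag_count >= 0),
          "minute table: quality_flag_count must be >= 0",
          "actisleep_integrity_error")
  key <- paste(df$subject_id, df$day_index, df$minute_of_day)
  .assert(!anyDuplicated(key),
          "minute table: duplicate (subject_id, day_index, minute_of_day)",
          "actisleep_integrity_error")
  df
}

.decode_race <- function(x) {
  if (is.numeric(x)) {
    # NHANES RIDRETH3: 1 Mexican American, 2 other Hispanic, 3 NH White,
    # 4 NH Black, 6 NH Asian, 7 other/multi
    map <- c(`1` = "Mexican American", `2` = "Other", `3` = "NH White",
             `4` = "NH Black", `6` = "Other", `7` = "Other")
    out <- map[as.character(x)]
  } else {
    lx <- tolower(trimws(x))
    out <- rep(NA_character_, length(x))
    out[lx %in% c("nh white", "non-hispanic white", "white")] <- "NH White"
    out[lx %in% c("nh black", "non-hispanic black", "black")] <- "NH Black"
    out[lx %in% c("mexican american", "mex american", "mexican")] <-
      "Mexican American"
    out[lx %in% c("other", "other race", "other hispanic", "asian",
                  "nh asian", "other ethnicity", "multi-racial")] <- "Other"
  }
  out
}

#' Read a demographics / survey-design table
#'
#' Accepts NHANES DEMO variable names (SEQN, RIDAGEYR, RIAGENDR, RIDRETH3,
#' WTMEC2YR, SDMVSTRA, SDMVPSU) as aliases. Race is mapped to the 4-group
#' coding NH White / NH Black / Mexican American / Other (other Hispanic,
#' Asian and other ethnicity fold into Other). Subjects younger than 6 are
#' retained but flagged \code{eligible = FALSE}; the analytic filter is
#' applied downstream.
#'
#' @inheritParams read_minute_table
#' @return data.frame with columns \code{subject_id}, \code{age_years},
#'   \code{sex}, \code{race}, \code{weight_2yr}, \code{stratum}, \code{psu},
#'   \code{cycle}, \code{eligible}
#' @export
read_demographics <- function(path, format = c("csv", "parquet")) {
  df <- .read_table(path, format)
  df <- .apply_aliases(df, .DEMO_ALIASES, "demographics table")
  if (nrow(df) == 0) { df$eligible <- logical(0); return(df) }
  if (is.numeric(df$sex)) {
    .assert(all(df$sex %in% 1:2),
            "demographics: numeric sex codes must be 1 (male) or 2 (female)",
            "actisleep_parse_error")
    df$sex <- .SEX_LEVELS[df$sex]
  } else {
    df$sex <- tolower(trimws(df$sex))
  }
  bad <- which(!df$sex %in% .SEX_LEVELS)
  .assert(length(bad) == 0,
          sprintf("demographics: unknown sex value at row %d", bad[1]),
          "actisleep_parse_error")
  race <- .decode_race(df$race)
  bad <- which(is.na(race))
  .assert(length(bad) == 0,
          sprintf("demographics: unknown race code '%s' at row %d",
                  as.character(df$race[bad[1]]), bad[1]),
          "actisleep_parse_error")
  df$race <- race
  .assert(all(is.finite(df$weight_2yr) & df$weight_2yr > 0),
          "demographics: weight_2yr must be positive",
          "actisleep_validation_error")
  if (is.numeric(df$cycle)) df$cycle <- ifelse(df$cycle %% 2 == 1, "A", "B")
  df$eligible <- df$age_years >= 6
  df
}

#' Write pipeline result tables with a schema manifest
#'
#' Writes each named table to \code{dir} in a deterministic column order and
#' records a JSON manifest (\code{manifest.json}) listing every file with its
#' row count and column schema. A \code{sleep_efficiency} column, if present,
#' is validated to lie in [0, 1].
#'
#' @param tables named list of data.frames
#' @param dir output directory (created if needed)
#' @param format \code{"csv"} or \code{"parquet"}
#' @return invisibly, the manifest as a list
#' @export
write_outputs <- function(tables, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  .assert(is.list(tables) && length(tables) > 0 &&
            !is.null(names(tables)) && all(nzchar(names(tables))),
          "tables must be a non-empty named list", "actisleep_io_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(dir), sprintf("cannot create directory %s", dir),
          "actisleep_io_error")
  files <- list()
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    df <- df[, sort(names(df)), drop = FALSE]  # deterministic column order
    if ("sleep_efficiency" %in% names(df)) {
      ok <- is.na(df$sleep_efficiency) |
        (df$sleep_efficiency >= 0 & df$sleep_efficiency <= 1)
      .assert(all(ok), sprintf("%s: sleep_efficiency outside [0, 1]", nm),
              "actisleep_validation_error")
    }
    fn <- file.path(dir, paste0(nm, ".", format))
    .write_table(df, fn, format)
    files[[nm]] <- list(file = basename(fn), n_rows = nrow(df),
                        columns = as.list(vapply(df, function(c)
                          class(c)[1], character(1))))
  }
  manifest <- list(format = format, tables = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
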