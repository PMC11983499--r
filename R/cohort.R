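#' Read a long-format diagnosis table
#'
#' Reads dated first-diagnosis events (one row per patient, condition and
#' date) from CSV, validates columns and dates, removes exact duplicate rows
#' and drops events outside the study window.
#'
#' @param path Path to a CSV file with header
#'   \code{patient_id,condition,date,source}; dates ISO-8601.
#' @param study_window Length-2 character or Date vector giving the first and
#'   last admissible diagnosis date. Default 2000-01-01 to 2021-12-31.
#' @param vocabulary Optional character vector of admissible condition labels.
#'   When supplied, unknown labels are an error unless
#'   \code{allow_unknown = TRUE}.
#' @param allow_unknown Pass through condition labels absent from
#'   \code{vocabulary} instead of erroring.
#' @return A \code{data.frame} with columns \code{patient_id}, \code{condition},
#'   \code{date} (class \code{Date}) and \code{source}; the number of rows
#'   dropped by the window filter is attached as attribute
#'   \code{"n_dropped_window"}.
#' @export
read_diagnoses <- function(path, study_window = c("2000-01-01", "2021-12-31"),
                           vocabulary = NULL, allow_unknown = FALSE) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = "")
  required <- c("patient_id", "condition", "date")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("diagnosis table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"source" %in% names(dt)) dt[, source := "unspecified"]
  dt[is.na(source), source := "unspecified"]
  if (nrow(dt) == 0L) {
    out <- data.frame(patient_id = character(), condition = character(),
                      date = as.Date(character()), source = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped_window") <- 0L
    return(out)
  }
  if (anyNA(dt$condition) || any(!nzchar(dt$condition)))
    stop("empty condition label in diagnosis table")
  parsed <- as.Date(dt$date, format = "%Y-%m-%d")
  if (anyNA(parsed))
    stop("unparseable date(s) in diagnosis table, e.g. ",
         dt$date[which(is.na(parsed))[1L]])
  dt[, date := parsed]
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(dt$condition), vocabulary)
    if (length(unknown) && !allow_unknown)
      stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  window <- as.Date(study_window)
  in_window <- dt$date >= window[1L] & dt$date <= window[2L]
  n_dropped <- sum(!in_window)
  if (n_dropped > 0L)
    warning(sprintf("%d diagnosis record(s) outside the study window dropped",
                    n_dropped))
  dt <- unique(dt[in_window])
  out <- as.data.frame(dt)
  attr(out, "n_dropped_window") <- n_dropped
  out
}

#' Read a patient demographics table
#'
#' @param path CSV with header
#'   \code{patient_id,sex,birth_date,death_date,wimd,ethnicity}
#'   (blank fields are missing; dates ISO-8601).
#' @return A \code{data.frame} of patient profiles; \code{wimd} integer 1-5
#'   or NA.
#' @export
read_demographics <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = "")
  required <- c("patient_id", "sex", "birth_date")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("demographics table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(dt$patient_id))
    stop("duplicate patient_id in demographics: ",
         dt$patient_id[anyDuplicated(dt$patient_id)])
  for (col in c("death_date", "wimd", "ethnicity"))
    if (!col %in% names(dt)) dt[, (col) := NA_character_]
  parse_date <- function(x, what) {
    out <- as.Date(x, format = "%Y-%m-%d")
    if (any(is.na(out) & !is.na(x)))
      stop("unparseable ", what, " in demographics")
    out
  }
  out <- data.frame(
    patient_id = dt$patient_id,
    sex        = dt$sex,
    birth_date = parse_date(dt$birth_date, "birth_date"),
    death_date = parse_date(dt$death_date, "death_date"),
    wimd       = as.integer(dt$wimd),
    ethnicity  = dt$ethnicity,
    stringsAsFactors = FALSE
  )
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("sex must be 'male' or 'female'; offending patient(s): ",
         paste(utils::head(out$patient_id[bad_sex], 5L), collapse = ", "))
  bad_death <- !is.na(out$death_date) & out$death_date < out$birth_date
  if (any(bad_death))
    stop("death_date before birth_date for patient(s): ",
         paste(utils::head(out$patient_id[bad_death], 5L), collapse = ", "))
  out
}

#' Load and validate the two required input tables
#'
#' Convenience wrapper around [read_diagnoses()] and [read_demographics()]
#' driven by a run configuration (see [read_run_config()]).
#'
#' @param diagnosis_path,demographics_path CSV paths.
#' @param config A list with at least \code{study_window}; see
#'   [default_run_config()].
#' @return \code{list(diagnoses =, profiles =)}.
#' @export
load_inputs <- function(diagnosis_path, demographics_path,
                        config = default_run_config()) {
  diagnoses <- read_diagnoses(diagnosis_path,
                              study_window = config$study_window,
                              vocabulary = config$vocabulary,
                              allow_unknown = isTRUE(config$allow_unknown))
  profiles <- read_demographics(demographics_path)
  list(diagnoses = diagnoses, profiles = profiles)
}

#' Reduce diagnosis records to per-patient first-diagnosis chronologies
#'
#' For every (patient, condition) the earliest recorded date over all sources
#' is kept. The result is ordered within each patient by date, ties broken by
#' condition label (ascending), so each patient's rows read as their
#' chronological sequence of first diagnoses.
#'
#' @param records Data frame with columns \code{patient_id}, \code{condition},
#'   \code{date}.
#' @return A \code{data.frame} (class \code{"first_diag_table"}) with columns
#'   \code{patient_id}, \code{condition}, \code{date}.
#' @export
first_diagnosis_table <- function(records) {
  stopifnot(all(c("patient_id", "condition", "date") %in% names(records)))
  dt <- data.table::as.data.table(records)[, c("patient_id", "condition", "date")]
  dt <- dt[, list(date = min(date)), by = c("patient_id", "condition")]
  data.table::setorderv(dt, c("patient_id", "date", "condition"))
  out <- as.data.frame(dt)
  class(out) <- c("first_diag_table", "data.frame")
  out
}

#' Per-patient count of distinct long-term conditions
#'
#' @param fdt A [first_diagnosis_table()].
#' @param patient_ids Optional vector of patients to report (patients with no
#'   diagnoses get count 0).
#' @return Named integer vector.
#' @export
ltc_counts <- function(fdt, patient_ids = NULL) {
  counts <- table(fdt$patient_id)
  if (is.null(patient_ids)) patient_ids <- names(counts)
  out <- integer(length(patient_ids))
  names(out) <- patient_ids
  hit <- intersect(patient_ids, names(counts))
  out[hit] <- as.integer(counts[hit])
  out
}

# Age in completed years at a reference date.
age_at <- function(birth_date, ref_date) {
  by <- as.POSIXlt(birth_date); ry <- as.POSIXlt(ref_date)
  age <- ry$year - by$year
  before_birthday <- (ry$mon < by$mon) | (ry$mon == by$mon & ry$mday < by$mday)
  age - as.integer(before_birthday)
}

#' Assign sex/age strata
#'
#' Partitions the cohort into four strata (2 sexes x 2 age bands). Age is
#' computed in completed years at a per-patient reference date chosen by
#' \code{reference_policy}:
#' \describe{
#'   \item{followup_end}{min(death date, study end) — the default.}
#'   \item{first_ltc}{date of the patient's first recorded diagnosis
#'     (requires \code{fdt}); patients without diagnoses fall back to
#'     followup end.}
#'   \item{midpoint}{midpoint between study start and followup end.}
#' }
#' Patients aged exactly the threshold fall in the upper band (\code{ge_45}).
#'
#' @param profiles Demographics data frame; rows missing sex or birth date are
#'   excluded (count attached as attribute \code{"n_excluded"}).
#' @param study_window Length-2 date vector.
#' @param age_threshold Band boundary in years (default 45).
#' @param reference_policy One of \code{"followup_end"}, \code{"first_ltc"},
#'   \code{"midpoint"}.
#' @param fdt First-diagnosis table, needed for \code{"first_ltc"}.
#' @return Data frame with columns \code{patient_id}, \code{sex},
#'   \code{age_years}, \code{age_band} (\code{under_45}/\code{ge_45} for the
#'   default threshold), \code{stratum} (e.g. \code{"male_ge_45"}).
#' @export
assign_strata <- function(profiles, study_window = c("2000-01-01", "2021-12-31"),
                          age_threshold = 45,
                          reference_policy = c("followup_end", "first_ltc",
                                               "midpoint"),
                          fdt = NULL) {
  reference_policy <- match.arg(reference_policy)
  window <- as.Date(study_window)
  ok <- !is.na(profiles$sex) & !is.na(profiles$birth_date)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    warning(sprintf("%d patient(s) missing sex or birth_date excluded",
                    n_excluded))
  p <- profiles[ok, , drop = FALSE]
  followup_end <- pmin(
    data.table::fifelse(is.na(p$death_date), window[2L], p$death_date),
    window[2L])
  ref <- switch(reference_policy,
    followup_end = followup_end,
    midpoint = window[1L] + as.numeric(followup_end - window[1L]) / 2,
    first_ltc = {
      if (is.null(fdt))
        stop("reference_policy 'first_ltc' requires fdt")
      first <- tapply(fdt$date, fdt$patient_id, min)
      r <- followup_end
      hit <- match(p$patient_id, names(first))
      r[!is.na(hit)] <- as.Date(first[hit[!is.na(hit)]],
                                origin = "1970-01-01")
      r
    })
  age <- age_at(p$birth_date, ref)
  band_labels <- c(sprintf("under_%d", age_threshold),
                   sprintf("ge_%d", age_threshold))
  band <- ifelse(age >= age_threshold, band_labels[2L], band_labels[1L])
  out <- data.frame(patient_id = p$patient_id, sex = p$sex, age_years = age,
                    age_band = band,
                    stratum = paste(p$sex, band, sep = "_"),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

# 1-decimal percentage used throughout the descriptive tables.
percent_of <- function(n, total) round(100 * n / total, 1)

#' Descriptive cohort summary
#'
#' Computes, per group, the patient count and percentage of the cohort, mean
#' and SD of the per-patient number of long-term conditions (LTCs), the count
#' and percentage with multiple LTCs (two or more), and the count and
#' percentage with physical-mental multimorbidity (at least one mental and one
#' physical condition). Percentages use the group size as denominator and are
#' rounded to one decimal.
#'
#' @param fdt A [first_diagnosis_table()].
#' @param profiles Demographics (all profiled patients count, including those
#'   with zero recorded LTCs).
#' @param grouping One of \code{"all"}, \code{"sex"}, \code{"age"},
#'   \code{"ethnicity"}, \code{"wimd"}.
#' @param condition_map Data frame \code{condition}, \code{system_chapter},
#'   \code{is_mental} (logical), e.g. [default_condition_map()].
#' @param strata Output of [assign_strata()]; required for
#'   \code{grouping = "age"}.
#' @return Data frame with one row per group: \code{group}, \code{n},
#'   \code{percent}, \code{mean_ltc}, \code{sd_ltc}, \code{n_mltc},
#'   \code{percent_mltc}, \code{n_pm_mltc}, \code{percent_pm_mltc},
#'   \code{degenerate} (TRUE for empty groups, whose means are NA).
#' @export
descriptive_summary <- function(fdt, profiles, grouping = "all",
                                condition_map = default_condition_map(),
                                strata = NULL) {
  grouping <- match.arg(grouping, c("all", "sex", "age", "ethnicity", "wimd"))
  ids <- profiles$patient_id
  counts <- ltc_counts(fdt, ids)
  mental_set <- condition_map$condition[isTRUE_vec(condition_map$is_mental)]
  has_mental <- tapply(fdt$condition %in% mental_set, fdt$patient_id, any)
  has_physical <- tapply(!(fdt$condition %in% mental_set), fdt$patient_id, any)
  pm <- stats::setNames(rep(FALSE, length(ids)), ids)
  hit <- intersect(ids, names(has_mental))
  pm[hit] <- has_mental[hit] & has_physical[hit]
  group <- switch(grouping,
    all = rep("all", length(ids)),
    sex = profiles$sex,
    ethnicity = ifelse(is.na(profiles$ethnicity), "Unknown",
                       profiles$ethnicity),
    wimd = ifelse(is.na(profiles$wimd), "Unknown",
                  as.character(profiles$wimd)),
    age = {
      if (is.null(strata)) stop("grouping 'age' requires strata")
      strata$age_band[match(ids, strata$patient_id)]
    })
  total <- length(ids)
  groups <- sort(unique(stats::na.omit(group)))
  rows <- lapply(groups, function(g) {
    sel <- !is.na(group) & group == g
    n <- sum(sel)
    k <- counts[sel]
    n_mltc <- sum(k >= 2L)
    n_pm <- sum(pm[sel])
    data.frame(group = g, n = n, percent = percent_of(n, total),
               mean_ltc = if (n) round(mean(k), 1) else NA_real_,
               sd_ltc = if (n > 1) round(stats::sd(k), 1) else NA_real_,
               n_mltc = n_mltc,
               percent_mltc = if (n) percent_of(n_mltc, n) else NA_real_,
               n_pm_mltc = n_pm,
               percent_pm_mltc = if (n) percent_of(n_pm, n) else NA_real_,
               degenerate = n == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# TRUE where x is TRUE (NA- and type-safe for logical/character flags).
isTRUE_vec <- function(x) {
  if (is.character(x)) x <- tolower(x) %in% c("true", "1", "yes")
  !is.na(x) & as.logical(x)
}

#' Default condition vocabulary and system-chapter mapping
#'
#' A 40-condition long-term-condition vocabulary with a body-system chapter
#' and a mental-health flag per condition, shipped as
#' \code{inst/extdata/condition_map.csv}. The mapping is a curated
#' approximation suitable for examples and synthetic cohorts; analyses of real
#' data should supply their own mapping via the same three-column format.
#'
#' @return Data frame \code{condition}, \code{system_chapter},
#'   \code{is_mental}.
#' @export
default_condition_map <- function() {
  path <- system.file("extdata", "condition_map.csv", package = "mltctraj",
                      mustWork = TRUE)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  map$is_mental <- isTRUE_vec(map$is_mental)
  map
}
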