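#' Default ICD-10 chapter lookup
#'
#' Code-range table mapping ICD-10 three-character prefixes to body-system
#' chapters, shipped as \code{inst/extdata/icd10_chapters.csv}.
#'
#' @return Data frame \code{start}, \code{end}, \code{chapter}.
#' @export
icd10_chapter_map <- function() {
  path <- system.file("extdata", "icd10_chapters.csv", package = "mltctraj",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Map ICD-10 codes (e.g. "I21", "I21.9") to chapter labels; unmappable codes
# become "other".
icd10_to_chapter <- function(codes, chapter_map = icd10_chapter_map()) {
  prefix <- toupper(substr(gsub("[^A-Za-z0-9].*$", "", codes), 1L, 3L))
  valid <- grepl("^[A-Z][0-9]{2}$", prefix)
  out <- rep("other", length(codes))
  for (r in seq_len(nrow(chapter_map))) {
    hit <- valid & prefix >= chapter_map$start[r] & prefix <= chapter_map$end[r]
    out[hit] <- chapter_map$chapter[r]
  }
  n_other <- sum(out == "other")
  if (n_other > 0L)
    message(n_other, " cause-of-death code(s) could not be mapped to an ",
            "ICD-10 chapter; bucketed as 'other'")
  out
}

#' System-chapter composition of a trajectory cluster
#'
#' Each condition slot of each trajectory (3 slots per trajectory)
#' contributes once; the percentage of slots falling in each body-system
#' chapter is reported, so the values sum to 100.
#'
#' @param cluster_trajs Data frame \code{c1}, \code{c2}, \code{c3} for the
#'   cluster's trajectories.
#' @param condition_map Data frame \code{condition}, \code{system_chapter}
#'   (e.g. [default_condition_map()]).
#' @return Named numeric vector of percentages, decreasing.
#' @export
system_distribution <- function(cluster_trajs,
                                condition_map = default_condition_map()) {
  if (nrow(cluster_trajs) == 0L) stop("empty cluster")
  slots <- c(cluster_trajs$c1, cluster_trajs$c2, cluster_trajs$c3)
  chapter <- condition_map$system_chapter[match(slots,
                                                condition_map$condition)]
  if (anyNA(chapter))
    stop("condition(s) missing from the system map: ",
         paste(unique(slots[is.na(chapter)]), collapse = ", "))
  tab <- 100 * table(chapter) / length(slots)
  sort(stats::setNames(as.numeric(tab), names(tab)), decreasing = TRUE)
}

#' Unique patients supporting a trajectory cluster
#'
#' @param cluster_trajs Trajectories of one cluster, carrying a
#'   \code{patients} list column (see [build_trajectories()] with
#'   \code{keep_membership = TRUE}).
#' @return Character vector of unique patient ids (the union over the
#'   cluster's trajectories).
#' @export
cluster_patients <- function(cluster_trajs) {
  stopifnot("patients" %in% names(cluster_trajs))
  unique(unlist(cluster_trajs$patients, use.names = FALSE))
}

#' Mortality and long-hospital-stay summary for a patient set
#'
#' Mortality percent is the share of the patients who died during the study
#' period. The mortality rate accrues person-time from each patient's first
#' recorded diagnosis (or an alternative origin) to death or study end and
#' reports deaths per 100 person-years. The long-stay percent is the share
#' of patients with at least one hospital stay strictly longer than
#' \code{long_stay_days} days.
#'
#' @param patients Character vector of patient ids (non-empty).
#' @param profiles Demographics (needs \code{patient_id}, \code{death_date}).
#' @param stays Data frame \code{patient_id}, \code{admission_date},
#'   \code{discharge_date} (may be empty).
#' @param fdt First-diagnosis table (person-time origin under the default
#'   policy).
#' @param long_stay_days Strict threshold in days (default 4: a long stay
#'   lasts more than 4 days).
#' @param study_window Length-2 date vector; follow-up is censored at its
#'   end.
#' @param origin_policy Person-time origin: \code{"first_ltc"} (default),
#'   \code{"study_start"}.
#' @return \code{list(mortality_percent =, rate_per_100py =,
#'   long_stay_percent =, person_years =, n_deaths =, undefined_rate =)}.
#' @export
mortality_and_stays <- function(patients, profiles, stays, fdt,
                                long_stay_days = 4,
                                study_window = c("2000-01-01", "2021-12-31"),
                                origin_policy = c("first_ltc",
                                                  "study_start")) {
  stopifnot(length(patients) > 0L)
  origin_policy <- match.arg(origin_policy)
  window <- as.Date(study_window)
  prof <- profiles[match(patients, profiles$patient_id), , drop = FALSE]
  deceased <- !is.na(prof$death_date) & prof$death_date <= window[2L]
  mortality_percent <- 100 * sum(deceased) / length(patients)
  origin <- if (origin_policy == "study_start") {
    rep(window[1L], length(patients))
  } else {
    first <- tapply(as.numeric(fdt$date), fdt$patient_id, min)
    o <- rep(as.numeric(window[1L]), length(patients))
    hit <- match(patients, names(first))
    o[!is.na(hit)] <- first[hit[!is.na(hit)]]
    as.Date(o, origin = "1970-01-01")
  }
  end <- as.Date(ifelse(deceased, prof$death_date, window[2L]),
                 origin = "1970-01-01")
  person_years <- sum(pmax(as.numeric(end - origin), 0)) / 365.25
  undefined_rate <- person_years <= 0
  rate <- if (undefined_rate) NA_real_ else
    100 * sum(deceased) / person_years
  if (undefined_rate)
    warning("zero person-years; mortality rate undefined")
  long_stay_percent <- if (nrow(stays) == 0L) 0 else {
    dur <- as.numeric(as.Date(stays$discharge_date) -
                        as.Date(stays$admission_date))
    long_ids <- unique(stays$patient_id[dur > long_stay_days])
    100 * sum(patients %in% long_ids) / length(patients)
  }
  list(mortality_percent = mortality_percent, rate_per_100py = rate,
       long_stay_percent = long_stay_percent, person_years = person_years,
       n_deaths = sum(deceased), undefined_rate = undefined_rate)
}

#' Leading causes of death in a patient set
#'
#' Distribution of underlying-cause ICD-10 chapters among the deceased
#' members of a patient set, truncated to the top chapters.
#'
#' @param patients Character vector of patient ids.
#' @param deaths Data frame \code{patient_id}, \code{death_date},
#'   \code{icd10_underlying}.
#' @param chapter_map Code-range table, see [icd10_chapter_map()].
#' @param top_n Number of chapters reported (default 5; ties broken by
#'   chapter label).
#' @return Named numeric vector of percentages over the deceased (empty when
#'   no deaths).
#' @export
causes_of_death <- function(patients, deaths,
                            chapter_map = icd10_chapter_map(), top_n = 5) {
  dd <- deaths[deaths$patient_id %in% patients, , drop = FALSE]
  if (nrow(dd) == 0L) return(stats::setNames(numeric(0), character(0)))
  chapters <- icd10_to_chapter(dd$icd10_underlying, chapter_map)
  tab <- 100 * table(chapters) / nrow(dd)
  dist <- stats::setNames(as.numeric(tab), names(tab))
  dist <- dist[order(-dist, names(dist))]
  utils::head(dist, top_n)
}

#' Characterise every cluster of a stratum
#'
#' Combines [system_distribution()], [cluster_patients()],
#' [mortality_and_stays()] and [causes_of_death()] into one summary row per
#' cluster, sorted by unique patient count descending.
#'
#' @param trajs Trajectories with \code{patients} membership list column.
#' @param labels Cluster label per trajectory.
#' @param profiles,stays,deaths Cohort tables.
#' @param fdt First-diagnosis table.
#' @param condition_map,chapter_map Mapping tables.
#' @param study_window,long_stay_days Passed through.
#' @return Data frame with one row per cluster: \code{cluster},
#'   \code{n_traj}, \code{n_patients}, \code{top_systems} (formatted
#'   string), \code{mortality_percent}, \code{rate_per_100py},
#'   \code{long_stay_percent}, \code{top_cod} (formatted string).
#' @export
characterise_clusters <- function(trajs, labels, profiles, stays, deaths,
                                  fdt,
                                  condition_map = default_condition_map(),
                                  chapter_map = icd10_chapter_map(),
                                  study_window = c("2000-01-01",
                                                   "2021-12-31"),
                                  long_stay_days = 4) {
  stopifnot(nrow(trajs) == length(labels))
  fmt <- function(x) paste(sprintf("%s (%.1f%%)", names(x), x),
                           collapse = ", ")
  rows <- lapply(sort(unique(labels)), function(cl) {
    sel <- labels == cl
    ct <- trajs[sel, , drop = FALSE]
    pts <- cluster_patients(ct)
    sys <- system_distribution(ct, condition_map)
    ms <- mortality_and_stays(pts, profiles, stays, fdt,
                              long_stay_days = long_stay_days,
                              study_window = study_window)
    cod <- causes_of_death(pts, deaths, chapter_map)
    data.frame(cluster = cl, n_traj = nrow(ct), n_patients = length(pts),
               top_systems = fmt(utils::head(sys, 5L)),
               mortality_percent = round(ms$mortality_percent, 1),
               rate_per_100py = round(ms$rate_per_100py, 1),
               long_stay_percent = round(ms$long_stay_percent, 1),
               top_cod = fmt(cod), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_patients), , drop = FALSE]
}
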