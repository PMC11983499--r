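#' Specification of a synthetic EHR cohort
#'
#' Describes a cohort generator with known ground truth: per-condition
#' baseline first-diagnosis hazards, planted directed pair dependencies
#' (a first diagnosis of C1 multiplies the subsequent hazard of C2), and
#' planted condition communities (a per-patient gamma frailty shared by the
#' conditions of a community, creating co-occurrence and, downstream, graph
#' communities).
#'
#' The defaults emulate the structure of a Welsh adult intellectual-
#' disability cohort observed 2000-2021: 20 long-term conditions spanning
#' six body systems, two condition communities (a cardio-metabolic/renal one
#' and a neuro-psychiatric/digestive one), annual baseline hazards giving
#' 20-40\% lifetime prevalence over the 22-year window, a 52.3:47.7
#' male:female ratio, ages uniform 18-80 at study start, and background
#' mortality and hospital-stay processes.
#'
#' @param n_patients Cohort size (default 2000).
#' @param conditions Character vector of condition labels; must appear in
#'   \code{condition_map}.
#' @param baseline_rates Named annual hazard per condition (defaults between
#'   0.010 and 0.024).
#' @param planted_pairs Data frame \code{c1}, \code{c2}, \code{lift},
#'   \code{mean_lag_days}; each condition may be the target (\code{c2}) of
#'   at most one planted pair.
#' @param communities Named list of condition label vectors partitioning
#'   \code{conditions}.
#' @param community_frailty_var Variance of the mean-1 gamma frailty shared
#'   within a community (0 disables co-occurrence; default 1).
#' @param sex_ratio Probability of male (default 0.523).
#' @param age_range Age bounds at study start (default 18-80).
#' @param death_rate Annual death hazard (default 0.015).
#' @param stay_rate Annual hospital-stay rate (default 0.25).
#' @param stay_meanlog,stay_sdlog Log-normal stay duration parameters in
#'   days (defaults log(3) and 0.9).
#' @param study_window Length-2 date vector (default 2000-01-01 to
#'   2021-12-31).
#' @param condition_map Vocabulary mapping, see [default_condition_map()].
#' @param seed Integer RNG seed (default 1).
#' @return Object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 2000,
                        conditions = default_synthetic_conditions(),
                        baseline_rates = NULL,
                        planted_pairs = default_planted_pairs(),
                        communities = default_communities(),
                        community_frailty_var = 1,
                        sex_ratio = 0.523,
                        age_range = c(18, 80),
                        death_rate = 0.015,
                        stay_rate = 0.25,
                        stay_meanlog = log(3), stay_sdlog = 0.9,
                        study_window = c("2000-01-01", "2021-12-31"),
                        condition_map = default_condition_map(),
                        seed = 1) {
  stopifnot(n_patients >= 1, length(conditions) >= 1)
  if (is.null(baseline_rates)) {
    rates <- seq(0.010, 0.024, length.out = length(conditions))
    baseline_rates <- stats::setNames(rates, conditions)
  }
  stopifnot(all(conditions %in% names(baseline_rates)),
            all(baseline_rates[conditions] > 0))
  if (nrow(planted_pairs)) {
    stopifnot(all(planted_pairs$lift >= 1),
              all(c(planted_pairs$c1, planted_pairs$c2) %in% conditions),
              !anyDuplicated(planted_pairs$c2))
  }
  members <- unlist(communities, use.names = FALSE)
  if (!setequal(members, conditions) || anyDuplicated(members))
    stop("communities must partition the condition list")
  missing_map <- setdiff(conditions, condition_map$condition)
  if (length(missing_map))
    stop("condition(s) missing from condition_map: ",
         paste(missing_map, collapse = ", "))
  out <- list(n_patients = n_patients, conditions = conditions,
              baseline_rates = baseline_rates[conditions],
              planted_pairs = planted_pairs, communities = communities,
              community_frailty_var = community_frailty_var,
              sex_ratio = sex_ratio, age_range = age_range,
              death_rate = death_rate, stay_rate = stay_rate,
              stay_meanlog = stay_meanlog, stay_sdlog = stay_sdlog,
              study_window = as.Date(study_window),
              condition_map = condition_map, seed = seed)
  class(out) <- "cohort_spec"
  out
}

#' @rdname cohort_spec
#' @export
default_synthetic_conditions <- function() {
  c("hypertension", "coronary heart disease", "cardiac arrhythmias",
    "heart failure", "diabetes", "chronic kidney disease", "anaemia",
    "thyroid disorders", "chronic airway diseases", "stroke",
    "epilepsy", "cerebral palsy", "mental illness", "insomnia",
    "reflux disorders", "chronic constipation", "dysphagia",
    "chronic arthritis", "chronic pain conditions", "neuropathic pain")
}

#' @rdname cohort_spec
#' @export
default_communities <- function() {
  list(
    cardiometabolic = c("hypertension", "coronary heart disease",
                        "cardiac arrhythmias", "heart failure", "diabetes",
                        "chronic kidney disease", "anaemia",
                        "thyroid disorders", "chronic airway diseases",
                        "stroke"),
    neurodigestive = c("epilepsy", "cerebral palsy", "mental illness",
                       "insomnia", "reflux disorders",
                       "chronic constipation", "dysphagia",
                       "chronic arthritis", "chronic pain conditions",
                       "neuropathic pain"))
}

#' @rdname cohort_spec
#' @export
default_planted_pairs <- function() {
  data.frame(
    c1 = c("hypertension", "diabetes", "cardiac arrhythmias",
           "epilepsy", "mental illness", "reflux disorders"),
    c2 = c("chronic kidney disease", "coronary heart disease",
           "heart failure", "mental illness", "insomnia", "anaemia"),
    lift = c(4, 4, 4, 4, 4, 4),
    mean_lag_days = rep(365, 6),
    stringsAsFactors = FALSE)
}

# Topological order of conditions so every planted trigger (c1) is generated
# before its target (c2); planted dependencies must be acyclic.
condition_generation_order <- function(conditions, planted_pairs) {
  order_out <- character(0)
  remaining <- conditions
  repeat {
    blocked <- planted_pairs$c2[planted_pairs$c1 %in% remaining]
    ready <- setdiff(remaining, blocked)
    if (!length(ready)) {
      if (length(remaining)) stop("planted pair dependencies contain a cycle")
      break
    }
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  order_out
}

#' Generate a synthetic EHR cohort
#'
#' Per patient, condition onsets are drawn as exponential waiting times at
#' the condition's baseline hazard, multiplied by the patient's community
#' frailty. For a planted pair C1 -> C2, C2's hazard is multiplied by
#' \code{lift} from a trigger time equal to C1's onset plus an exponential
#' lag with the configured mean (piecewise-exponential sampling). Onsets are
#' recorded as first-diagnosis events when they fall inside the study window
#' and before the patient's death. Deaths and hospital stays are drawn
#' independently of the diagnosis process. Fully reproducible from
#' \code{spec$seed}.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class \code{"synthetic_cohort"}: list with
#'   \code{diagnoses}, \code{profiles}, \code{stays}, \code{deaths} (data
#'   frames matching the package's input schemas) and \code{ground_truth}
#'   (planted pairs and per-condition community labels).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  window <- spec$study_window
  window_years <- as.numeric(window[2L] - window[1L]) / 365.25
  ids <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  age0 <- stats::runif(n, spec$age_range[1L], spec$age_range[2L])
  birth_date <- window[1L] - round(age0 * 365.25)

  # Per-patient community frailties (mean-1 gamma).
  v <- spec$community_frailty_var
  frailty <- sapply(spec$communities, function(members) {
    if (v > 0) stats::rgamma(n, shape = 1 / v, scale = v) else rep(1, n)
  })
  if (is.null(dim(frailty))) frailty <- matrix(frailty, nrow = n)
  colnames(frailty) <- names(spec$communities)
  community_of <- stats::setNames(
    rep(names(spec$communities), lengths(spec$communities)),
    unlist(spec$communities, use.names = FALSE))

  # death_rate 0 turns mortality off entirely; shared death truncation
  # induces positive dependence between conditions, so the independence
  # (null) configuration needs it disabled.
  death_time <- if (spec$death_rate > 0)
    stats::rexp(n, rate = spec$death_rate) else rep(Inf, n)
  died <- death_time <= window_years
  death_date <- as.Date(rep(NA, n), origin = "1970-01-01")
  death_date[died] <- window[1L] + round(death_time[died] * 365.25)

  # Condition onset times in years since study start.
  onset <- matrix(Inf, nrow = n, ncol = length(spec$conditions),
                  dimnames = list(ids, spec$conditions))
  gen_order <- condition_generation_order(spec$conditions,
                                          spec$planted_pairs)
  for (cond in gen_order) {
    h0 <- spec$baseline_rates[[cond]] * frailty[, community_of[[cond]]]
    e <- stats::rexp(n, rate = 1)
    row <- which(spec$planted_pairs$c2 == cond)
    if (length(row) == 1L) {
      trigger_onset <- onset[, spec$planted_pairs$c1[row]]
      lag <- stats::rexp(n, rate = 365.25 /
                              spec$planted_pairs$mean_lag_days[row])
      t_trig <- trigger_onset + lag
      lift <- spec$planted_pairs$lift[row]
      h_at_trig <- h0 * t_trig
      t <- ifelse(e <= h_at_trig | is.infinite(t_trig),
                  e / h0,
                  t_trig + (e - h_at_trig) / (lift * h0))
    } else {
      t <- e / h0
    }
    onset[, cond] <- t
  }

  keep <- is.finite(onset) & onset <= window_years &
    onset <= rep(death_time, times = ncol(onset))
  idx <- which(keep, arr.ind = TRUE)
  diagnoses <- data.frame(
    patient_id = ids[idx[, 1L]],
    condition = spec$conditions[idx[, 2L]],
    date = window[1L] + round(onset[keep] * 365.25),
    source = sample(c("primary_care", "secondary_care"),
                    sum(keep), replace = TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date,
                               diagnoses$condition), , drop = FALSE]
  rownames(diagnoses) <- NULL

  profiles <- data.frame(
    patient_id = ids, sex = sex, birth_date = birth_date,
    death_date = death_date, wimd = sample(1:5, n, replace = TRUE),
    ethnicity = NA_character_, stringsAsFactors = FALSE)

  followup <- pmin(death_time, window_years)
  n_stays <- stats::rpois(n, lambda = spec$stay_rate * followup)
  stay_pid <- rep(ids, n_stays)
  stay_fup <- rep(followup, n_stays)
  admit <- window[1L] + round(stats::runif(length(stay_pid), 0,
                                           stay_fup) * 365.25)
  duration <- round(stats::rlnorm(length(stay_pid), spec$stay_meanlog,
                                  spec$stay_sdlog))
  stays <- data.frame(patient_id = stay_pid, admission_date = admit,
                      discharge_date = admit + duration,
                      stringsAsFactors = FALSE)
  stays <- stays[order(stays$patient_id, stays$admission_date), ,
                 drop = FALSE]
  rownames(stays) <- NULL

  cod_pool <- c("I21", "I50", "I64", "C34", "C18", "J18", "J44", "G40",
                "F03", "K70", "E11", "N18")
  cod_prob <- c(0.16, 0.12, 0.08, 0.08, 0.05, 0.12, 0.08, 0.08,
                0.07, 0.05, 0.06, 0.05)
  deaths <- data.frame(
    patient_id = ids[died],
    death_date = death_date[died],
    icd10_underlying = sample(cod_pool, sum(died), replace = TRUE,
                              prob = cod_prob),
    stringsAsFactors = FALSE)
  rownames(deaths) <- NULL

  out <- list(diagnoses = diagnoses, profiles = profiles, stays = stays,
              deaths = deaths,
              ground_truth = list(planted_pairs = spec$planted_pairs,
                                  communities = community_of))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$profiles), "patients,",
      nrow(x$diagnoses), "first-diagnosis events,",
      nrow(x$deaths), "deaths,", nrow(x$stays), "hospital stays\n")
  invisible(x)
}

#' Expected (planted) community label of each trajectory
#'
#' Labels each trajectory by the planted condition community containing the
#' majority of its three conditions; ties are broken in favour of the first
#' community in the specification.
#'
#' @param spec The [cohort_spec()] that generated the cohort.
#' @param trajs Trajectories produced by the pipeline on that cohort.
#' @return Character vector of community names, one per trajectory.
#' @export
planted_cluster_labels <- function(spec, trajs) {
  community_of <- stats::setNames(
    rep(names(spec$communities), lengths(spec$communities)),
    unlist(spec$communities, use.names = FALSE))
  vapply(seq_len(nrow(trajs)), function(r) {
    comms <- community_of[c(trajs$c1[r], trajs$c2[r], trajs$c3[r])]
    counts <- table(factor(comms, levels = names(spec$communities)))
    names(counts)[which.max(counts)]
  }, character(1))
}

#' Write a synthetic cohort to CSV files plus a ground-truth JSON
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$profiles, file.path(dir, "demographics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$stays, file.path(dir, "stays.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$deaths, file.path(dir, "deaths.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(planted_pairs = cohort$ground_truth$planted_pairs,
         communities = as.list(cohort$ground_truth$communities)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
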