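#' Default run configuration
#'
#' All tunable constants of the pipeline in one list: the study window, the
#' 45-year age-band threshold, the pair-screening rules (at least 10 shared
#' patients, six months = 183 days minimum separation, Bonferroni-adjusted
#' alpha 0.001, binomial direction alpha 0.05), the trajectory support
#' filter (10 patients), network and clustering options, and the long-stay
#' threshold (more than 4 days).
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    study_window = c("2000-01-01", "2021-12-31"),
    age_threshold = 45,
    reference_policy = "followup_end",
    min_shared = 10,
    min_gap_days = 183,
    alpha_pair = 0.001,
    alpha_direction = 0.05,
    min_traj_patients = 10,
    require_all_pairs = FALSE,
    edge_mode = "consecutive",
    frequency_mode = "trajectories",
    normalise_frequencies = FALSE,
    self_similarity = "max_sim",
    k_min = 2,
    k_max = 10,
    cluster_seed = 42,
    min_cluster_size = 3,
    min_silhouette = 0.05,
    long_stay_days = 4,
    origin_policy = "first_ltc",
    vocabulary = NULL,
    allow_unknown = TRUE
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override [default_run_config()]; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return Named configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  stopifnot(cfg$min_shared > 0, cfg$min_gap_days >= 0,
            cfg$alpha_pair > 0, cfg$alpha_direction > 0,
            cfg$min_traj_patients > 0, cfg$k_min >= 2)
  cfg
}

# Analyse one stratum end to end: pairs -> trajectories -> network ->
# clustering -> characterisation.
run_stratum <- function(fdt, patient_ids, profiles, stays, deaths, cfg,
                        condition_map) {
  pairs <- pair_analysis(fdt, patient_ids,
                         min_shared = cfg$min_shared,
                         min_gap_days = cfg$min_gap_days,
                         alpha_pair = cfg$alpha_pair,
                         alpha_direction = cfg$alpha_direction)
  trajs <- build_trajectories(pairs, fdt, patient_ids,
                              min_gap_days = cfg$min_gap_days,
                              min_patients = cfg$min_traj_patients,
                              require_all_pairs = cfg$require_all_pairs,
                              keep_membership = TRUE)
  res <- list(n_patients = length(patient_ids),
              n_candidate_pairs = attr(pairs, "n_candidates"),
              n_significant_pairs = nrow(pairs),
              n_candidate_trajectories = attr(trajs, "n_candidates"),
              n_trajectories = nrow(trajs),
              pairs = pairs, trajectories = trajs,
              graph = NULL, similarity = NULL, clusters = NULL,
              summary = NULL, clustering_skipped = FALSE)
  if (nrow(trajs) < cfg$k_min + 1) {
    # Too few trajectories to resolve structure; a single cluster (or none).
    res$clustering_skipped <- TRUE
    if (nrow(trajs) > 0) {
      res$clusters <- list(labels = rep(1L, nrow(trajs)), k = 1L,
                           ch_scores = numeric(0), seed = cfg$cluster_seed,
                           embedding_dim = 0L, degenerate = TRUE,
                           mean_silhouette = NA_real_,
                           min_cluster_size = nrow(trajs))
      class(res$clusters) <- "cluster_report"
    }
  } else {
    res$graph <- build_condition_graph(
      trajs, edge_mode = cfg$edge_mode,
      frequency_mode = cfg$frequency_mode,
      normalise = isTRUE(cfg$normalise_frequencies))
    res$similarity <- trajectory_similarity_matrix(
      trajs, res$graph, self_similarity = cfg$self_similarity)
    res$clusters <- select_k(unclass(res$similarity),
                             k_min = cfg$k_min, k_max = cfg$k_max,
                             seed = cfg$cluster_seed,
                             min_cluster_size = cfg$min_cluster_size,
                             min_silhouette = cfg$min_silhouette)
  }
  if (!is.null(res$clusters) && nrow(trajs) > 0) {
    res$summary <- characterise_clusters(
      trajs, res$clusters$labels, profiles, stays, deaths, fdt,
      condition_map = condition_map,
      study_window = cfg$study_window,
      long_stay_days = cfg$long_stay_days)
  }
  res
}

empty_stays <- function() {
  data.frame(patient_id = character(), admission_date = as.Date(character()),
             discharge_date = as.Date(character()), stringsAsFactors = FALSE)
}

empty_deaths <- function() {
  data.frame(patient_id = character(), death_date = as.Date(character()),
             icd10_underlying = character(), stringsAsFactors = FALSE)
}

#' Run the full trajectory-mining pipeline
#'
#' Orchestrates cohort ingestion, per-stratum pair screening, trajectory
#' composition, condition-network construction, spectral clustering and
#' cluster characterisation, optionally writing all artifacts (CSV, JSON,
#' GraphML) plus a run manifest to an output directory. Rerunning with
#' identical inputs and configuration reproduces identical outputs.
#'
#' @param diagnoses Long-format diagnosis records (see [read_diagnoses()]).
#' @param profiles Demographics (see [read_demographics()]).
#' @param stays,deaths Optional hospital-stay and death tables (empty by
#'   default).
#' @param config Configuration list, see [default_run_config()].
#' @param condition_map Vocabulary mapping, see [default_condition_map()].
#' @param out_dir Output directory; NULL (default) skips file output.
#' @return Object of class \code{"pipeline_result"}: list with
#'   \code{strata} (per-stratum results), \code{fdt}, \code{stratum_table},
#'   \code{descriptives} and \code{manifest}.
#' @export
run_pipeline <- function(diagnoses, profiles, stays = empty_stays(),
                         deaths = empty_deaths(),
                         config = default_run_config(),
                         condition_map = default_condition_map(),
                         out_dir = NULL) {
  fdt <- first_diagnosis_table(diagnoses)
  strata <- assign_strata(profiles, study_window = config$study_window,
                          age_threshold = config$age_threshold,
                          reference_policy = config$reference_policy,
                          fdt = fdt)
  descriptives <- descriptive_summary(fdt, profiles, "all", condition_map)
  stratum_names <- sort(unique(strata$stratum))
  results <- lapply(stratum_names, function(s) {
    run_stratum(fdt, strata$patient_id[strata$stratum == s],
                profiles, stays, deaths, config, condition_map)
  })
  names(results) <- stratum_names
  manifest <- list(
    package_version = as.character(utils::packageVersion("mltctraj")),
    config = config[setdiff(names(config), "vocabulary")],
    n_patients = nrow(profiles),
    n_diagnosis_records = nrow(diagnoses),
    strata = lapply(results, function(r) {
      list(n_patients = r$n_patients,
           n_candidate_pairs = r$n_candidate_pairs,
           n_significant_pairs = r$n_significant_pairs,
           n_candidate_trajectories = r$n_candidate_trajectories,
           n_trajectories = r$n_trajectories,
           n_clustered = if (is.null(r$clusters)) 0L
                         else length(r$clusters$labels),
           k = if (is.null(r$clusters)) NA_integer_ else r$clusters$k,
           clustering_skipped = r$clustering_skipped)
    }))
  out <- list(strata = results, fdt = fdt, stratum_table = strata,
              descriptives = descriptives, manifest = manifest)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$manifest$n_patients, "patients,",
      length(x$strata), "strata\n")
  for (s in names(x$strata)) {
    r <- x$strata[[s]]
    cat(sprintf("  %-16s %5d patients, %3d significant pairs, %3d trajectories, k = %s\n",
                s, r$n_patients, r$n_significant_pairs, r$n_trajectories,
                if (is.null(r$clusters)) "-" else r$clusters$k))
  }
  invisible(x)
}

# Write every per-stratum artifact plus the manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$descriptives,
                   file.path(out_dir, "descriptive_summary.csv"),
                   row.names = FALSE)
  for (s in names(result$strata)) {
    r <- result$strata[[s]]
    sdir <- file.path(out_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    if (nrow(r$pairs))
      write_pair_table(r$pairs, file.path(sdir, "pairs.csv"))
    trajs <- r$trajectories
    if (nrow(trajs)) {
      tt <- data.frame(c1 = trajs$c1, c2 = trajs$c2, c3 = trajs$c3,
                       n_patients = trajs$n_patients, stratum = s,
                       stringsAsFactors = FALSE)
      utils::write.csv(tt, file.path(sdir, "trajectories.csv"),
                       row.names = FALSE)
    }
    if (!is.null(r$graph))
      write_condition_graph(r$graph,
                            edge_list_path = file.path(sdir, "edges.csv"),
                            graphml_path = file.path(sdir, "graph.graphml"))
    if (!is.null(r$similarity))
      utils::write.csv(as.data.frame(unclass(r$similarity)),
                       file.path(sdir, "similarity.csv"))
    if (!is.null(r$clusters)) {
      cl <- data.frame(trajectory = paste(trajs$c1, trajs$c2, trajs$c3,
                                          sep = "|"),
                       c1 = trajs$c1, c2 = trajs$c2, c3 = trajs$c3,
                       cluster = r$clusters$labels,
                       stringsAsFactors = FALSE)
      utils::write.csv(cl, file.path(sdir, "clusters.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(k = r$clusters$k, ch_scores = as.list(r$clusters$ch_scores),
             seed = r$clusters$seed, degenerate = r$clusters$degenerate,
             mean_silhouette = r$clusters$mean_silhouette),
        file.path(sdir, "cluster_report.json"), auto_unbox = TRUE,
        digits = NA, na = "null")
    }
    if (!is.null(r$summary))
      utils::write.csv(r$summary, file.path(sdir, "cluster_summary.csv"),
                       row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
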