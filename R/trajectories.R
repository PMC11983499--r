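# Directed edges implied by significant pairs: a preferred order contributes
# that order only; no preferred order ("none") contributes both orders.
directed_edges <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    c1 <- pairs$c1[r]; c2 <- pairs$c2[r]
    out[[length(out) + 1L]] <- switch(pairs$direction[r],
      forward  = data.frame(from = c1, to = c2, stringsAsFactors = FALSE),
      backward = data.frame(from = c2, to = c1, stringsAsFactors = FALSE),
      none     = data.frame(from = c(c1, c2), to = c(c2, c1),
                            stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Compose ordered three-condition trajectories from significant pairs
#'
#' Chains every pair of directed edges sharing a middle condition: if C1->C2
#' and C2->C3 are available (a pair without a preferred order contributes
#' both directions), the candidate trajectory C1->C2->C3 is formed. The
#' first and last condition must differ; the chaining pair (C1, C3) is not
#' itself required to be significant unless \code{require_all_pairs}.
#'
#' @param pairs Output of [pair_analysis()] (needs \code{c1}, \code{c2},
#'   \code{direction}).
#' @param require_all_pairs Also require the (C1, C3) pair to be a
#'   significant pair in a compatible direction (stricter composition rule;
#'   default FALSE).
#' @return Data frame \code{c1}, \code{c2}, \code{c3}, one row per candidate
#'   trajectory, in lexicographic order.
#' @export
compose_triples <- function(pairs, require_all_pairs = FALSE) {
  edges <- directed_edges(pairs)
  empty <- data.frame(c1 = character(), c2 = character(), c3 = character(),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(empty)
  out <- list()
  for (mid in unique(edges$to)) {
    ins <- edges$from[edges$to == mid]
    outs <- edges$to[edges$from == mid]
    if (!length(ins) || !length(outs)) next
    grid <- expand.grid(c1 = ins, c3 = outs, stringsAsFactors = FALSE)
    grid <- grid[grid$c1 != grid$c3, , drop = FALSE]
    if (nrow(grid))
      out[[length(out) + 1L]] <- data.frame(c1 = grid$c1, c2 = mid,
                                            c3 = grid$c3,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  if (require_all_pairs) {
    key <- paste(edges$from, edges$to, sep = "\r")
    res <- res[paste(res$c1, res$c3, sep = "\r") %in% key, , drop = FALSE]
  }
  res <- res[order(res$c1, res$c2, res$c3), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count patients supporting an ordered trajectory
#'
#' A patient supports C1->C2->C3 when their first-diagnosis dates satisfy
#' date(C1) < date(C2) < date(C3) with each consecutive gap at least
#' \code{min_gap_days}. Diagnoses of other conditions in between are ignored
#' (the trajectory conditions only need to keep their chronological order).
#'
#' @param traj Character vector of ordered condition labels (length >= 2).
#' @param fdt A [first_diagnosis_table()].
#' @param patient_ids Patients to scan (default: all in \code{fdt}).
#' @param min_gap_days Minimum gap between consecutive trajectory conditions
#'   in days (default 183; 0 disables the gap rule but still requires a
#'   strictly increasing date order).
#' @param return_ids Return the supporting patient identifiers instead of
#'   the count.
#' @return Integer count, or character vector of patient ids when
#'   \code{return_ids}.
#' @export
count_supporting_patients <- function(traj, fdt,
                                      patient_ids = unique(fdt$patient_id),
                                      min_gap_days = 183,
                                      return_ids = FALSE) {
  stopifnot(length(traj) >= 2L, !anyDuplicated(traj))
  sub <- fdt[fdt$condition %in% traj & fdt$patient_id %in% patient_ids, ,
             drop = FALSE]
  m <- matrix(NA_real_, nrow = length(patient_ids), ncol = length(traj),
              dimnames = list(patient_ids, traj))
  if (nrow(sub))
    m[cbind(match(sub$patient_id, patient_ids),
            match(sub$condition, traj))] <- as.numeric(sub$date)
  ok <- !is.na(m[, 1L])
  for (l in seq_len(length(traj) - 1L)) {
    gap <- m[, l + 1L] - m[, l]
    ok <- ok & !is.na(gap) & gap >= min_gap_days & gap > 0
  }
  if (return_ids) patient_ids[ok] else sum(ok)
}

#' Deduplicate trajectories over the same condition set and filter by support
#'
#' Among trajectories visiting the same unordered set of three conditions,
#' only the most frequent sequence is retained (ties broken by the
#' lexicographically smallest sequence); trajectories supported by fewer
#' than \code{min_patients} patients are then dropped.
#'
#' @param trajs Data frame \code{c1}, \code{c2}, \code{c3},
#'   \code{n_patients}.
#' @param min_patients Minimum support (default 10).
#' @return The retained subset, sorted by \code{n_patients} descending then
#'   sequence.
#' @export
dedupe_and_filter <- function(trajs, min_patients = 10) {
  if (nrow(trajs) == 0L) return(trajs)
  seqs <- trajs[, c("c1", "c2", "c3")]
  set_key <- apply(seqs, 1L, function(x) paste(sort(x), collapse = "\r"))
  seq_key <- paste(trajs$c1, trajs$c2, trajs$c3, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(trajs)), set_key), function(rows) {
    best <- rows[trajs$n_patients[rows] == max(trajs$n_patients[rows])]
    best[order(seq_key[best])][1L]
  }), use.names = FALSE)
  out <- trajs[keep, , drop = FALSE]
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$c1, out$c2, out$c3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the shared trajectories for one stratum
#'
#' Runs composition, patient counting, deduplication and support filtering in
#' one call, optionally collecting per-trajectory supporting patient sets
#' (needed later for cluster characterisation).
#'
#' @param pairs Output of [pair_analysis()] for the stratum.
#' @param fdt A [first_diagnosis_table()].
#' @param patient_ids Stratum patients.
#' @param min_gap_days Gap rule passed to [count_supporting_patients()].
#' @param min_patients Support filter passed to [dedupe_and_filter()].
#' @param require_all_pairs Passed to [compose_triples()].
#' @param keep_membership Attach the supporting patient ids of each retained
#'   trajectory as a list column \code{patients}.
#' @return Data frame (class \code{"trajectories"}) \code{c1}, \code{c2},
#'   \code{c3}, \code{n_patients} (+ \code{patients} list column when
#'   requested), sorted by support descending.
#' @export
build_trajectories <- function(pairs, fdt, patient_ids,
                               min_gap_days = 183, min_patients = 10,
                               require_all_pairs = FALSE,
                               keep_membership = FALSE) {
  cand <- compose_triples(pairs, require_all_pairs = require_all_pairs)
  if (nrow(cand) == 0L) {
    out <- data.frame(c1 = character(), c2 = character(), c3 = character(),
                      n_patients = integer(), stringsAsFactors = FALSE)
    if (keep_membership) out$patients <- list()
    class(out) <- c("trajectories", "data.frame")
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  m <- date_matrix(fdt, patient_ids)
  support <- function(traj) {
    d1 <- m[, traj[1L]]; d2 <- m[, traj[2L]]; d3 <- m[, traj[3L]]
    g1 <- d2 - d1; g2 <- d3 - d2
    !is.na(g1) & !is.na(g2) & g1 >= min_gap_days & g1 > 0 &
      g2 >= min_gap_days & g2 > 0
  }
  cand$n_patients <- vapply(seq_len(nrow(cand)), function(r) {
    sum(support(c(cand$c1[r], cand$c2[r], cand$c3[r])))
  }, integer(1))
  out <- dedupe_and_filter(cand, min_patients = min_patients)
  if (keep_membership) {
    out$patients <- lapply(seq_len(nrow(out)), function(r) {
      patient_ids[support(c(out$c1[r], out$c2[r], out$c3[r]))]
    })
  }
  class(out) <- c("trajectories", "data.frame")
  attr(out, "n_candidates") <- nrow(cand)
  out
}
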