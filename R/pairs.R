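# Wide patient x condition matrix of first-diagnosis dates (numeric days,
# NA where the condition was never diagnosed). Rows = patients.
date_matrix <- function(fdt, patient_ids) {
  conditions <- sort(unique(fdt$condition))
  m <- matrix(NA_real_, nrow = length(patient_ids), ncol = length(conditions),
              dimnames = list(patient_ids, conditions))
  sub <- fdt[fdt$patient_id %in% patient_ids, , drop = FALSE]
  if (nrow(sub))
    m[cbind(match(sub$patient_id, patient_ids),
            match(sub$condition, conditions))] <- as.numeric(sub$date)
  m
}

#' Enumerate candidate condition pairs within a stratum
#'
#' A pair (C1, C2) qualifies when at least \code{min_shared} stratum patients
#' have both conditions with an absolute first-diagnosis separation of at
#' least \code{min_gap_days}. For every qualifying pair the full 2x2
#' contingency counts over the stratum population are returned, together with
#' the temporal direction counts (\code{n_forward}: C1 at least
#' \code{min_gap_days} before C2; \code{n_backward}: the reverse;
#' \code{n_close}: both present but closer than the gap, including same-day)
#' and the mean/SD of the absolute interval in years over all patients with
#' both conditions regardless of order.
#'
#' Pairs are stored with \code{c1 < c2} lexicographically; direction is
#' resolved later by [directionality_test()].
#'
#' @param fdt A [first_diagnosis_table()].
#' @param patient_ids Patients forming the stratum (the contingency-table
#'   denominator).
#' @param min_shared Minimum number of patients sharing both conditions at
#'   the required separation (default 10).
#' @param min_gap_days Minimum temporal separation in days (default 183,
#'   i.e. six months).
#' @return Data frame (class \code{"pair_counts"}) with one row per
#'   qualifying pair: \code{c1}, \code{c2}, \code{n_both}, \code{n_c1_only},
#'   \code{n_c2_only}, \code{n_neither}, \code{n_forward}, \code{n_backward},
#'   \code{n_close}, \code{mean_years}, \code{sd_years}.
#' @export
enumerate_candidate_pairs <- function(fdt, patient_ids, min_shared = 10,
                                      min_gap_days = 183) {
  stopifnot(length(patient_ids) > 0L)
  m <- date_matrix(fdt, patient_ids)
  n <- nrow(m)
  conds <- colnames(m)
  k <- length(conds)
  rows <- vector("list", if (k >= 2L) k * (k - 1L) / 2L else 0L)
  idx <- 0L
  for (i in seq_len(max(k - 1L, 0L))) {
    di <- m[, i]
    has_i <- !is.na(di)
    for (j in seq.int(i + 1L, k)) {
      dj <- m[, j]
      both <- has_i & !is.na(dj)
      n_both <- sum(both)
      if (n_both < min_shared) next
      diff_days <- dj[both] - di[both]          # >0: c1 first
      n_forward <- sum(diff_days >= min_gap_days)
      n_backward <- sum(-diff_days >= min_gap_days)
      if (n_forward + n_backward < min_shared) next
      idx <- idx + 1L
      abs_years <- abs(diff_days) / 365.25
      rows[[idx]] <- data.frame(
        c1 = conds[i], c2 = conds[j],
        n_both = n_both,
        n_c1_only = sum(has_i) - n_both,
        n_c2_only = sum(!is.na(dj)) - n_both,
        n_neither = n - sum(has_i | !is.na(dj)),
        n_forward = n_forward, n_backward = n_backward,
        n_close = n_both - n_forward - n_backward,
        mean_years = mean(abs_years),
        sd_years = if (n_both > 1L) stats::sd(abs_years) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (idx) do.call(rbind, rows[seq_len(idx)]) else
    data.frame(c1 = character(), c2 = character(), n_both = integer(),
               n_c1_only = integer(), n_c2_only = integer(),
               n_neither = integer(), n_forward = integer(),
               n_backward = integer(), n_close = integer(),
               mean_years = numeric(), sd_years = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("pair_counts", "data.frame")
  out
}

#' Fisher's exact test of association for one condition pair
#'
#' Two-sided exact test on the 2x2 contingency table (both / C1 only /
#' C2 only / neither). The reported odds ratio is the sample cross-product
#' ratio (infinite when an off-diagonal cell is zero), not the conditional
#' MLE. A table with a zero row or column margin carries no information about
#' association and is flagged degenerate with p = 1.
#'
#' @param pc One row of [enumerate_candidate_pairs()] output (or any list
#'   with \code{n_both}, \code{n_c1_only}, \code{n_c2_only},
#'   \code{n_neither}).
#' @return \code{list(p_value =, odds_ratio =, degenerate =)}.
#' @export
fisher_association <- function(pc) {
  a <- pc$n_both; b <- pc$n_c1_only; c <- pc$n_c2_only; d <- pc$n_neither
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = or, degenerate = TRUE))
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p_value = min(p, 1), odds_ratio = or, degenerate = FALSE)
}

#' Bonferroni selection of significant pairs
#'
#' Adjusts each Fisher p-value for the number of candidate pairs tested in
#' the stratum (\code{adjusted_p = min(1, m * p)}) and keeps pairs with
#' \code{adjusted_p < alpha}.
#'
#' @param results Data frame with a \code{fisher_p} column (one row per
#'   candidate pair; the row count is the correction family size).
#' @param alpha Significance threshold on the adjusted p (default 0.001).
#' @return The significant subset with an \code{adjusted_p} column added.
#' @export
bonferroni_select <- function(results, alpha = 0.001) {
  m <- nrow(results)
  if (m == 0L) {
    results$adjusted_p <- numeric(0)
    return(results)
  }
  results$adjusted_p <- pmin(1, m * results$fisher_p)
  results[results$adjusted_p < alpha, , drop = FALSE]
}

#' Exact binomial test of temporal direction for one pair
#'
#' Tests whether C1 precedes C2 more often than the reverse among patients
#' with both conditions separated by at least the screening gap
#' (\code{n_forward} vs \code{n_backward}; patients diagnosed closer than the
#' gap, \code{n_close}, carry no directional information and are excluded).
#' Two-sided exact binomial test with success probability 0.5. If
#' p < \code{alpha} the direction is the more frequent order, otherwise
#' \code{"none"} (no preferred order).
#'
#' @param pc One row of [enumerate_candidate_pairs()] output.
#' @param alpha Direction significance threshold (default 0.05).
#' @return \code{list(direction = "forward"|"backward"|"none",
#'   binomial_p =, undefined = )}; \code{undefined} is TRUE when no patient
#'   carries directional information (direction forced to \code{"none"},
#'   p = NA).
#' @export
directionality_test <- function(pc, alpha = 0.05) {
  nf <- pc$n_forward; nb <- pc$n_backward
  if (nf + nb == 0L)
    return(list(direction = "none", binomial_p = NA_real_, undefined = TRUE))
  p <- stats::binom.test(nf, nf + nb, p = 0.5,
                         alternative = "two.sided")$p.value
  direction <- if (p < alpha) {
    if (nf > nb) "forward" else "backward"
  } else "none"
  list(direction = direction, binomial_p = p, undefined = FALSE)
}

#' Full pair-screening stage for one stratum
#'
#' Enumerates candidate pairs, tests association (Fisher, Bonferroni) and
#' assigns temporal direction (binomial) in one call.
#'
#' @inheritParams enumerate_candidate_pairs
#' @param alpha_pair Adjusted-p threshold for association (default 0.001).
#' @param alpha_direction Binomial threshold for direction (default 0.05).
#' @return Data frame (class \code{"directed_pairs"}), one row per
#'   significant pair: pair counts plus \code{fisher_p}, \code{odds_ratio},
#'   \code{adjusted_p}, \code{direction}, \code{binomial_p},
#'   \code{n_patients} (= \code{n_both}), \code{mean_years},
#'   \code{sd_years}. The number of candidate pairs tested is attached as
#'   attribute \code{"n_candidates"}.
#' @export
pair_analysis <- function(fdt, patient_ids, min_shared = 10,
                          min_gap_days = 183, alpha_pair = 0.001,
                          alpha_direction = 0.05) {
  pc <- enumerate_candidate_pairs(fdt, patient_ids, min_shared = min_shared,
                                  min_gap_days = min_gap_days)
  if (nrow(pc)) {
    assoc <- lapply(seq_len(nrow(pc)), function(r) fisher_association(pc[r, ]))
    pc$fisher_p <- vapply(assoc, `[[`, numeric(1), "p_value")
    pc$odds_ratio <- vapply(assoc, `[[`, numeric(1), "odds_ratio")
    pc$degenerate <- vapply(assoc, `[[`, logical(1), "degenerate")
  } else {
    pc$fisher_p <- numeric(0); pc$odds_ratio <- numeric(0)
    pc$degenerate <- logical(0)
  }
  sig <- bonferroni_select(pc, alpha = alpha_pair)
  if (nrow(sig)) {
    dir <- lapply(seq_len(nrow(sig)),
                  function(r) directionality_test(sig[r, ],
                                                  alpha = alpha_direction))
    sig$direction <- vapply(dir, `[[`, character(1), "direction")
    sig$binomial_p <- vapply(dir, `[[`, numeric(1), "binomial_p")
  } else {
    sig$direction <- character(0); sig$binomial_p <- numeric(0)
  }
  sig$n_patients <- sig$n_both
  rownames(sig) <- NULL
  class(sig) <- c("directed_pairs", "data.frame")
  attr(sig, "n_candidates") <- nrow(pc)
  sig
}

#' Write a per-stratum pair table
#'
#' CSV export mirroring a published-style pair table: pair label with a
#' direction glyph (\code{->} for a preferred order, \code{<->} for none),
#' patient count, mean years (SD) and the p-values.
#'
#' @param pairs Output of [pair_analysis()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  glyph <- ifelse(pairs$direction == "none", "<->", "->")
  first <- ifelse(pairs$direction == "backward", pairs$c2, pairs$c1)
  second <- ifelse(pairs$direction == "backward", pairs$c1, pairs$c2)
  out <- data.frame(
    pair = paste(first, glyph, second),
    n_patients = pairs$n_patients,
    mean_years = round(pairs$mean_years, 1),
    sd_years = round(pairs$sd_years, 1),
    fisher_p = pairs$fisher_p,
    adjusted_p = pairs$adjusted_p,
    binomial_p = pairs$binomial_p,
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
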