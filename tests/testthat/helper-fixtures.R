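# Small cohort-construction helpers shared across test files.

# Long-format diagnosis records from (patient, condition, date) triples.
make_records <- function(...) {
  rows <- list(...)
  data.frame(
    patient_id = vapply(rows, `[[`, character(1), 1L),
    condition = vapply(rows, `[[`, character(1), 2L),
    date = as.Date(vapply(rows, `[[`, character(1), 3L)),
    source = "primary_care",
    stringsAsFactors = FALSE)
}

# Minimal demographics for a set of patient ids.
make_profiles <- function(ids, sex = "female", birth = "1970-06-15",
                          death = NA) {
  data.frame(patient_id = ids,
             sex = rep_len(sex, length(ids)),
             birth_date = as.Date(rep_len(birth, length(ids))),
             death_date = as.Date(rep_len(death, length(ids))),
             wimd = NA_integer_, ethnicity = NA_character_,
             stringsAsFactors = FALSE)
}

# A first-diagnosis table where `n_pairs` patients carry conditions A and B
# with the given day gap (A first), plus `n_extra` patients with A only.
make_pair_cohort <- function(n_pairs, gap_days, n_extra = 0,
                             start = as.Date("2005-01-01")) {
  ids <- sprintf("P%03d", seq_len(n_pairs + n_extra))
  rec <- data.frame(
    patient_id = c(ids[seq_len(n_pairs)], ids[seq_len(n_pairs)],
                   if (n_extra) ids[n_pairs + seq_len(n_extra)]),
    condition = c(rep("A", n_pairs), rep("B", n_pairs),
                  rep("A", n_extra)),
    date = c(rep(start, n_pairs), rep(start + gap_days, n_pairs),
             rep(start, n_extra)),
    source = "primary_care", stringsAsFactors = FALSE)
  list(fdt = first_diagnosis_table(rec), ids = ids)
}

# Noisy planted-block affinity matrix: `sizes` block sizes, `within` and
# `between` mean affinities, uniform noise of half-width `noise`.
planted_affinity <- function(sizes, within = 0.9, between = 0.05,
                             noise = 0.02) {
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  a <- matrix(between, n, n)
  for (b in seq_along(sizes)) a[labels == b, labels == b] <- within
  eps <- matrix(stats::runif(n * n, -noise, noise), n)
  a <- a + (eps + t(eps)) / 2
  a <- pmax(a, 0)
  diag(a) <- within
  list(affinity = a, labels = labels)
}
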