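dp <- function(...) {
  # Directed-pairs stub: list of c(c1, c2, direction).
  rows <- list(...)
  data.frame(c1 = vapply(rows, `[[`, character(1), 1L),
             c2 = vapply(rows, `[[`, character(1), 2L),
             direction = vapply(rows, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

test_that("triples chain directed pairs through a shared middle condition", {
  expect_equal(compose_triples(dp(c("A", "B", "forward"),
                                  c("B", "C", "forward"))),
               data.frame(c1 = "A", c2 = "B", c3 = "C",
                          stringsAsFactors = FALSE))

  # No shared middle condition: nothing to chain.
  expect_equal(nrow(compose_triples(dp(c("A", "B", "forward"),
                                       c("C", "D", "forward")))), 0L)

  # A<->B contributes both orders; only A->B feeds B->C.
  t1 <- compose_triples(dp(c("A", "B", "none"), c("B", "C", "forward")))
  expect_equal(t1, data.frame(c1 = "A", c2 = "B", c3 = "C",
                              stringsAsFactors = FALSE))
  # Adding A->C opens the chain B->A->C.
  t2 <- compose_triples(dp(c("A", "B", "none"), c("B", "C", "forward"),
                           c("A", "C", "forward")))
  expect_setequal(paste(t2$c1, t2$c2, t2$c3),
                  c("A B C", "B A C"))

  # backward direction reads as (c2 -> c1).
  t3 <- compose_triples(dp(c("B", "A", "backward"), c("C", "B", "backward")))
  expect_equal(paste(t3$c1, t3$c2, t3$c3), "A B C")

  # require_all_pairs demands the skip pair too.
  t4 <- compose_triples(dp(c("A", "B", "forward"), c("B", "C", "forward")),
                        require_all_pairs = TRUE)
  expect_equal(nrow(t4), 0L)
  t5 <- compose_triples(dp(c("A", "B", "forward"), c("B", "C", "forward"),
                           c("A", "C", "forward")),
                        require_all_pairs = TRUE)
  expect_equal(nrow(t5), 1L)
})

test_that("support counting respects order and consecutive gaps", {
  fdt <- first_diagnosis_table(make_records(
    list("P1", "A", "2000-01-01"), list("P1", "X", "2001-01-01"),
    list("P1", "B", "2002-01-01"), list("P1", "C", "2003-01-01"),
    list("P2", "A", "2000-01-01"), list("P2", "C", "2001-01-01"),
    list("P2", "B", "2002-01-01"),
    list("P3", "A", "2000-01-01"), list("P3", "B", "2000-04-10"),
    list("P3", "C", "2001-05-15")))

  # Intermediate condition X is ignored.
  expect_equal(count_supporting_patients(c("A", "B", "C"), fdt,
                                         patient_ids = "P1"), 1L)
  # Order violated (A, C, B): unsupported even though all three present.
  expect_equal(count_supporting_patients(c("A", "B", "C"), fdt,
                                         patient_ids = "P2"), 0L)
  # P3: B at A+100 days fails the 183-day gap rule; with the rule disabled
  # (gap 0) the strictly increasing order suffices.
  expect_equal(count_supporting_patients(c("A", "B", "C"), fdt,
                                         patient_ids = "P3"), 0L)
  expect_equal(count_supporting_patients(c("A", "B", "C"), fdt,
                                         patient_ids = "P3",
                                         min_gap_days = 0), 1L)
  expect_equal(count_supporting_patients(c("A", "B", "C"), fdt), 1L)
})

test_that("counting agrees with a brute-force patient scan", {
  co <- generate_cohort(cohort_spec(n_patients = 150, seed = 13))
  fdt <- first_diagnosis_table(co$diagnoses)
  ids <- co$profiles$patient_id
  conds <- sample(unique(fdt$condition), 6)
  set.seed(17)
  for (i in 1:10) {
    traj <- sample(conds, 3)
    brute <- sum(vapply(ids, function(p) {
      rows <- fdt[fdt$patient_id == p, ]
      d <- rows$date[match(traj, rows$condition)]
      !anyNA(d) && all(diff(as.numeric(d)) >= 183)
    }, logical(1)))
    expect_equal(count_supporting_patients(traj, fdt, ids), brute)
  }
})

test_that("relaxing the gap never decreases support", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 19))
  fdt <- first_diagnosis_table(co$diagnoses)
  ids <- co$profiles$patient_id
  traj <- c("hypertension", "chronic kidney disease", "anaemia")
  gaps <- c(365, 183, 90, 30, 0)
  counts <- vapply(gaps, function(g)
    count_supporting_patients(traj, fdt, ids, min_gap_days = g), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("deduplication keeps the most frequent sequence then filters", {
  tr <- function(c1, c2, c3, n)
    data.frame(c1 = c1, c2 = c2, c3 = c3, n_patients = n,
               stringsAsFactors = FALSE)

  out <- dedupe_and_filter(rbind(tr("A", "B", "C", 12), tr("A", "C", "B", 15)))
  expect_equal(paste(out$c1, out$c2, out$c3), "A C B")

  tie <- dedupe_and_filter(rbind(tr("B", "A", "C", 12), tr("A", "B", "C", 12)))
  expect_equal(paste(tie$c1, tie$c2, tie$c3), "A B C")

  expect_equal(nrow(dedupe_and_filter(tr("A", "B", "C", 9))), 0L)
  expect_equal(nrow(dedupe_and_filter(tr("A", "B", "C", 10))), 1L)
})

test_that("retained trajectories decompose into significant directed pairs", {
  co <- generate_cohort(cohort_spec(n_patients = 1200, seed = 23))
  fdt <- first_diagnosis_table(co$diagnoses)
  ids <- co$profiles$patient_id
  pairs <- pair_analysis(fdt, ids)
  trajs <- build_trajectories(pairs, fdt, ids)
  expect_gt(nrow(trajs), 0)
  edge_key <- local({
    e <- mltctraj:::directed_edges(pairs)
    paste(e$from, e$to)
  })
  for (r in seq_len(nrow(trajs))) {
    expect_true(paste(trajs$c1[r], trajs$c2[r]) %in% edge_key)
    expect_true(paste(trajs$c2[r], trajs$c3[r]) %in% edge_key)
  }
  # One trajectory per unordered condition set.
  sets <- apply(trajs[, c("c1", "c2", "c3")], 1,
                function(x) paste(sort(x), collapse = "|"))
  expect_false(anyDuplicated(sets) > 0)
  expect_true(all(trajs$n_patients >= 10))
})
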