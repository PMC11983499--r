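cmap <- data.frame(
  condition = c("epilepsy", "dementia", "reflux disorders", "dysphagia",
                "mental illness"),
  system_chapter = c("nervous", "nervous", "digestive", "digestive",
                     "mental"),
  is_mental = c(FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

tr <- function(c1, c2, c3, patients = list())
  data.frame(c1 = c1, c2 = c2, c3 = c3,
             patients = I(list(patients)), stringsAsFactors = FALSE)

test_that("system distribution counts condition slots and sums to 100", {
  one <- tr("epilepsy", "dementia", "reflux disorders")
  d <- system_distribution(one, cmap)
  expect_equal(unname(d["nervous"]), 200 / 3, tolerance = 1e-10)
  expect_equal(unname(d["digestive"]), 100 / 3, tolerance = 1e-10)

  expect_error(system_distribution(one[0, ], cmap), "empty cluster")
  expect_error(
    system_distribution(tr("epilepsy", "dementia", "novel"), cmap),
    "missing from the system map")

  four <- rbind(tr("epilepsy", "reflux disorders", "dysphagia"),
                tr("mental illness", "epilepsy", "dementia"),
                tr("dysphagia", "reflux disorders", "epilepsy"),
                tr("dementia", "mental illness", "reflux disorders"))
  d4 <- system_distribution(four, cmap)
  # Hand tally over 12 slots: nervous 5, digestive 5, mental 2.
  expect_equal(unname(d4[c("nervous", "digestive", "mental")]),
               100 * c(5, 5, 2) / 12, tolerance = 1e-10)
  expect_equal(sum(d4), 100, tolerance = 0.1)
})

test_that("cluster patients are the union of trajectory supports", {
  two <- rbind(tr("a", "b", "c", c("P1", "P2")),
               tr("b", "c", "d", c("P2", "P3")))
  expect_setequal(cluster_patients(two), c("P1", "P2", "P3"))
  disjoint <- rbind(tr("a", "b", "c", paste0("P", 1:5)),
                    tr("b", "c", "d", paste0("Q", 1:7)))
  expect_equal(length(cluster_patients(disjoint)), 12L)

  co <- generate_cohort(cohort_spec(n_patients = 800, seed = 41))
  fdt <- first_diagnosis_table(co$diagnoses)
  trajs <- build_trajectories(pair_analysis(fdt, co$profiles$patient_id),
                              fdt, co$profiles$patient_id,
                              keep_membership = TRUE)
  expect_gt(nrow(trajs), 1)
  brute <- unique(unlist(trajs$patients))
  expect_setequal(cluster_patients(trajs), brute)
})

test_that("mortality and long-stay follow their strict definitions", {
  window <- c("2000-01-01", "2009-12-31")
  ids <- paste0("P", 1:4)
  prof <- make_profiles(ids, death = c("2005-06-01", "2008-01-01", NA, NA))
  fdt <- first_diagnosis_table(make_records(
    list("P1", "A", "2000-01-01"), list("P2", "A", "2000-01-01"),
    list("P3", "A", "2000-01-01"), list("P4", "A", "2000-01-01")))
  stays <- data.frame(
    patient_id = c("P3", "P4"),
    admission_date = as.Date(c("2003-01-01", "2003-01-01")),
    discharge_date = as.Date(c("2003-01-05", "2003-01-06")),
    stringsAsFactors = FALSE)

  r <- mortality_and_stays(ids, prof, stays, fdt, study_window = window)
  expect_equal(r$mortality_percent, 50.0)    # 2 deceased of 4
  # Stay of exactly 4 days is not long (strict >); 5 days is.
  expect_equal(r$long_stay_percent, 25.0)

  # 1 death over ~50 person-years -> ~2.0 per 100 py.
  ids5 <- paste0("Q", 1:5)
  prof5 <- make_profiles(ids5, death = c("2009-12-31", NA, NA, NA, NA))
  fdt5 <- first_diagnosis_table(do.call(make_records, lapply(
    ids5, function(p) list(p, "A", "2000-01-01"))))
  r5 <- mortality_and_stays(ids5, prof5, mltctraj:::empty_stays(), fdt5,
                            study_window = window)
  expect_equal(r5$n_deaths, 1L)
  expect_equal(r5$rate_per_100py, 2.0, tolerance = 0.001)

  # Doubling follow-up halves the rate at fixed deaths.
  window2 <- c("2000-01-01", "2019-12-29")  # ~twice the follow-up
  prof5b <- make_profiles(ids5, death = c("2019-12-29", NA, NA, NA, NA))
  r5b <- mortality_and_stays(ids5, prof5b, mltctraj:::empty_stays(), fdt5,
                             study_window = window2)
  expect_equal(r5b$rate_per_100py, r5$rate_per_100py / 2, tolerance = 0.01)

  expect_true(r$mortality_percent >= 0 && r$mortality_percent <= 100)
})

test_that("causes of death aggregate to ICD-10 chapters", {
  d <- function(ids, codes)
    data.frame(patient_id = ids, death_date = as.Date("2010-01-01"),
               icd10_underlying = codes, stringsAsFactors = FALSE)

  one <- causes_of_death("P1", d("P1", "I21"))
  expect_equal(unname(one["circulatory"]), 100)

  four <- causes_of_death(paste0("P", 1:4),
                          d(paste0("P", 1:4), c("I21", "I50", "C34", "J18")))
  expect_equal(unname(four[c("circulatory", "neoplasms", "respiratory")]),
               c(50, 25, 25))
  expect_equal(sum(four), 100, tolerance = 0.1)

  expect_length(causes_of_death("P9", d("P1", "I21")), 0L)

  expect_message(
    odd <- causes_of_death("P1", d("P1", "XX99")),
    "could not be mapped")
  expect_equal(names(odd), "other")

  # top_n truncation with lexicographic tie-break.
  six <- causes_of_death(paste0("P", 1:6),
                         d(paste0("P", 1:6),
                           c("I21", "C34", "J18", "G40", "F03", "K70")))
  expect_length(six, 5L)
})

test_that("cluster characterisation composes one row per cluster", {
  co <- generate_cohort(cohort_spec(n_patients = 1000, seed = 43))
  fdt <- first_diagnosis_table(co$diagnoses)
  trajs <- build_trajectories(pair_analysis(fdt, co$profiles$patient_id),
                              fdt, co$profiles$patient_id,
                              keep_membership = TRUE)
  labels <- rep_len(1:2, nrow(trajs))
  summ <- characterise_clusters(trajs, labels, co$profiles, co$stays,
                                co$deaths, fdt)
  expect_equal(nrow(summ), 2L)
  expect_true(all(summ$mortality_percent >= 0 & summ$mortality_percent <= 100))
  expect_true(all(summ$n_patients <= 1000))
  expect_true(all(summ$n_traj > 0))
})
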