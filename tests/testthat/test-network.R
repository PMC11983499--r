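tr <- function(c1, c2, c3, n = 10)
  data.frame(c1 = c1, c2 = c2, c3 = c3, n_patients = n,
             stringsAsFactors = FALSE)

test_that("edge frequencies aggregate trajectory adjacencies undirected", {
  g1 <- build_condition_graph(tr("A", "B", "C"))
  expect_setequal(paste(g1$edges$condition_a, g1$edges$condition_b),
                  c("A B", "B C"))
  expect_true(all(g1$edges$frequency == 1))
  expect_true(all(g1$edges$weight == 1))

  g2 <- build_condition_graph(rbind(tr("A", "B", "C"), tr("A", "B", "D")))
  e2 <- g2$edges
  expect_equal(e2$frequency[e2$condition_a == "A" & e2$condition_b == "B"], 2)
  expect_equal(e2$weight[e2$condition_a == "A" & e2$condition_b == "B"], 0.5)
  expect_equal(e2$frequency[e2$condition_b == "C"], 1)
  expect_equal(e2$frequency[e2$condition_b == "D"], 1)

  # Reversed trajectory contributes the same undirected adjacencies.
  g3 <- build_condition_graph(rbind(tr("A", "B", "C"), tr("C", "B", "A")))
  expect_true(all(g3$edges$frequency == 2))

  # all_pairs mode adds the skip edge.
  g4 <- build_condition_graph(tr("A", "B", "C"), edge_mode = "all_pairs")
  expect_equal(nrow(g4$edges), 3L)

  # patient-weighted frequencies.
  g5 <- build_condition_graph(tr("A", "B", "C", n = 25),
                              frequency_mode = "patients")
  expect_true(all(g5$edges$frequency == 25))

  expect_equal(length(build_condition_graph(tr("A", "B", "C")[0, ])$nodes), 0L)
})

test_that("condition similarity is inverse shortest-path length", {
  # Triangle with w(A-B)=0.25, w(B-C)=0.5, w(A-C)=1: the two-hop detour
  # (0.75) beats the direct edge, so sim(A,C) = 1/0.75.
  g <- make_condition_graph(c("A", "B", "C"), data.frame(
    condition_a = c("A", "B", "A"), condition_b = c("B", "C", "C"),
    frequency = c(4, 2, 1), weight = c(0.25, 0.5, 1),
    stringsAsFactors = FALSE))
  expect_equal(condition_similarity(g, "A", "C"), 1 / 0.75)
  expect_equal(condition_similarity(g, "A", "B"), 4)
  expect_equal(condition_similarity(g, "A", "A"), 4)  # 1/w_min convention
  expect_error(condition_similarity(g, "A", "Z"), "not in graph")

  # Disconnected pair has similarity 0; adjacent f=1 pair similarity 1.
  g2 <- build_condition_graph(rbind(tr("A", "B", "C"), tr("D", "E", "F")))
  expect_equal(condition_similarity(g2, "A", "D"), 0)
  expect_equal(condition_similarity(g2, "A", "B"), 1)
})

test_that("Dijkstra agrees with independent shortest-path oracles", {
  set.seed(101)
  for (i in 1:40) {
    fix <- random_graph_fixture(sample(3:8, 1))
    d_pkg <- igraph::distances(fix$graph$graph, algorithm = "dijkstra",
                               weights = igraph::E(fix$graph$graph)$weight)
    d_pkg <- d_pkg[rownames(fix$w), colnames(fix$w)]
    d_fw <- floyd_warshall(fix$w)
    expect_equal(unname(d_pkg), unname(d_fw), tolerance = 1e-12)
    # Enumeration oracle on a couple of node pairs.
    n <- nrow(fix$w)
    for (j in 1:2) {
      ij <- sample(n, 2)
      expect_equal(unname(d_pkg[ij[1], ij[2]]),
                   enumerate_shortest(fix$w, ij[1], ij[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("trajectory similarity matrix follows the pairwise-mean formula", {
  # Chain A-B-C (single trajectory): sim(A,B)=sim(B,C)=1, sim(A,C)=1/2,
  # self-similarity 1/w_min = 1, so sim(t,t) = (3 + 2 + 2 + 1)/9 = 8/9.
  trajs <- tr("A", "B", "C")
  g <- build_condition_graph(trajs)
  s <- trajectory_similarity_matrix(trajs, g)
  expect_equal(unname(s[1, 1]), 8 / 9)

  # Disconnected components: zero cross-similarity, symmetric, non-negative.
  trajs2 <- rbind(tr("A", "B", "C"), tr("D", "E", "F"))
  g2 <- build_condition_graph(trajs2)
  s2 <- trajectory_similarity_matrix(trajs2, g2)
  expect_equal(unname(s2[1, 2]), 0)
  expect_equal(unclass(s2), t(unclass(s2)))
  expect_true(all(s2 >= 0))

  # Permuting trajectory order permutes rows/columns consistently.
  co <- generate_cohort(cohort_spec(n_patients = 1000, seed = 31))
  fdt <- first_diagnosis_table(co$diagnoses)
  trajs3 <- build_trajectories(pair_analysis(fdt, co$profiles$patient_id),
                               fdt, co$profiles$patient_id)
  g3 <- build_condition_graph(trajs3)
  s3 <- trajectory_similarity_matrix(trajs3, g3)
  expect_equal(unclass(s3), t(unclass(s3)))
  set.seed(1)
  perm <- sample(nrow(trajs3))
  s3p <- trajectory_similarity_matrix(trajs3[perm, ], g3)
  expect_equal(unname(unclass(s3p)), unname(unclass(s3)[perm, perm]))
})

test_that("similarities never decrease when a trajectory is added", {
  base <- rbind(tr("A", "B", "C"), tr("B", "C", "D"), tr("C", "D", "E"))
  extra <- rbind(base, tr("A", "B", "D"))
  g0 <- build_condition_graph(base)
  g1 <- build_condition_graph(extra)
  s0 <- mltctraj:::condition_similarity_matrix(g0, "zero")
  s1 <- mltctraj:::condition_similarity_matrix(g1, "zero")
  common <- g0$nodes
  expect_true(all(s1[common, common] - s0[common, common] >= -1e-12))
})

test_that("unit frequencies keep all reachable similarities in (0, 1]", {
  # Each trajectory on disjoint-ish adjacencies so every f = 1.
  trajs <- rbind(tr("A", "B", "C"), tr("C", "D", "E"), tr("E", "F", "A"))
  g <- build_condition_graph(trajs)
  expect_true(all(g$edges$frequency == 1))
  s <- mltctraj:::condition_similarity_matrix(g, "zero")
  off <- s[upper.tri(s)]
  expect_true(all(off > 0 & off <= 1))
})
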