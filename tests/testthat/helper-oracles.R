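# Independent oracles used against the package implementations.

# Two-sided Fisher p by full enumeration of the hypergeometric support with
# choose(); sums the point probabilities not exceeding the observed one
# (with the conventional 1 + 1e-7 tie tolerance).
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  point <- function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }
  probs <- vapply(lo:hi, point, numeric(1))
  obs <- point(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided exact binomial p at success probability 1/2 by tail summation.
binom_oracle_p <- function(x, n) {
  probs <- choose(n, 0:n) / 2^n
  obs <- probs[x + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Shortest-path oracle 1: hand-written Floyd-Warshall on a weight matrix
# (Inf where no edge); exact for positive weights.
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Shortest-path oracle 2: exhaustive enumeration of simple paths (use only
# on small graphs).
enumerate_shortest <- function(w, from, to) {
  n <- nrow(w)
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return()
    if (node == to) { best <<- len; return() }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(w[node, nxt]))
        recurse(nxt, `[<-`(visited, nxt, TRUE), len + w[node, nxt])
    }
  }
  recurse(from, `[<-`(rep(FALSE, n), from, TRUE), 0)
  best
}

# Random weighted undirected graph as a weight matrix plus the matching
# condition_graph object (frequencies 1..5, weights 1/f).
random_graph_fixture <- function(n_nodes, edge_prob = 0.35) {
  nodes <- paste0("c", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  freq <- sample(1:5, nrow(pairs), replace = TRUE)
  w <- matrix(Inf, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  if (nrow(pairs)) {
    w[pairs] <- 1 / freq
    w[pairs[, 2:1, drop = FALSE]] <- 1 / freq
  }
  edges <- data.frame(condition_a = nodes[pairs[, 1L]],
                      condition_b = nodes[pairs[, 2L]],
                      frequency = freq, weight = 1 / freq,
                      stringsAsFactors = FALSE)
  list(w = w, graph = make_condition_graph(nodes, edges))
}

# Build a condition_graph object directly from an edge table (bypasses
# build_condition_graph so arbitrary weights can be tested).
make_condition_graph <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("condition_a", "condition_b")], directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- edges$weight
  out <- list(nodes = nodes, edges = edges, graph = g)
  class(out) <- "condition_graph"
  out
}
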