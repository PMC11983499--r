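#' Build the undirected condition network from trajectories
#'
#' Every trajectory contributes its consecutive condition pairs as
#' undirected edges (C1->C2->C3 gives C1-C2 and C2-C3; with
#' \code{edge_mode = "all_pairs"}, also C1-C3). The edge frequency f(e) is
#' the number of trajectories containing that adjacency, each trajectory
#' counted once; the edge weight is its reciprocal, w(e) = 1/f(e), so
#' frequently co-traversed condition pairs lie closer in the network. With
#' \code{frequency_mode = "patients"} each trajectory instead contributes its
#' supporting patient count to f(e). \code{normalise = TRUE} divides all
#' frequencies by the maximum so the smallest weight is 1 and all
#' shortest-path similarities fall in (0, 1].
#'
#' @param trajs Data frame with columns \code{c1}, \code{c2}, \code{c3}
#'   (and \code{n_patients} for \code{frequency_mode = "patients"}).
#' @param edge_mode \code{"consecutive"} (default) or \code{"all_pairs"}.
#' @param frequency_mode \code{"trajectories"} (default) or
#'   \code{"patients"}.
#' @param normalise Rescale frequencies by their maximum (default FALSE,
#'   the literal inverse-frequency weighting).
#' @return Object of class \code{"condition_graph"}: a list with
#'   \code{nodes} (character), \code{edges} (data frame
#'   \code{condition_a,condition_b,frequency,weight}) and \code{graph}
#'   (the underlying weighted \pkg{igraph} object).
#' @export
build_condition_graph <- function(trajs,
                                  edge_mode = c("consecutive", "all_pairs"),
                                  frequency_mode = c("trajectories",
                                                     "patients"),
                                  normalise = FALSE) {
  edge_mode <- match.arg(edge_mode)
  frequency_mode <- match.arg(frequency_mode)
  if (nrow(trajs) == 0L) {
    edges <- data.frame(condition_a = character(), condition_b = character(),
                        frequency = numeric(), weight = numeric(),
                        stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    out <- list(nodes = character(), edges = edges, graph = g)
    class(out) <- "condition_graph"
    return(out)
  }
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(trajs))) {
    seq_r <- c(trajs$c1[r], trajs$c2[r], trajs$c3[r])
    pairs <- if (edge_mode == "consecutive") {
      list(seq_r[1:2], seq_r[2:3])
    } else {
      utils::combn(seq_r, 2L, simplify = FALSE)
    }
    w <- if (frequency_mode == "patients") trajs$n_patients[r] else 1
    keys <- unique(vapply(pairs,
                          function(p) paste(sort(p), collapse = "\r"),
                          character(1)))
    for (key in keys)
      assign(key, (if (exists(key, acc)) get(key, acc) else 0) + w, acc)
  }
  keys <- sort(ls(acc))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  freq <- vapply(keys, get, numeric(1), envir = acc)
  if (normalise) freq <- freq / max(freq)
  edges <- data.frame(condition_a = ab[, 1L], condition_b = ab[, 2L],
                      frequency = unname(freq), weight = 1 / unname(freq),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(trajs$c1, trajs$c2, trajs$c3)))
  g <- igraph::graph_from_data_frame(
    edges[, c("condition_a", "condition_b")], directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- edges$weight
  out <- list(nodes = nodes, edges = edges, graph = g)
  class(out) <- "condition_graph"
  out
}

#' @export
print.condition_graph <- function(x, ...) {
  cat("condition_graph:", length(x$nodes), "conditions,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("  edge frequency range:", min(x$edges$frequency), "-",
        max(x$edges$frequency), "\n")
  invisible(x)
}

# All-pairs weighted shortest-path (Dijkstra) matrix between conditions,
# plus the self-similarity convention on the diagonal.
condition_similarity_matrix <- function(graph,
                                        self_similarity = c("max_sim",
                                                            "zero")) {
  self_similarity <- match.arg(self_similarity)
  d <- igraph::distances(graph$graph, algorithm = "dijkstra",
                         weights = igraph::E(graph$graph)$weight)
  sim <- 1 / d                      # Inf distance -> 0 similarity
  sim[is.infinite(d)] <- 0
  diag(sim) <- switch(self_similarity,
    max_sim = if (nrow(graph$edges)) 1 / min(graph$edges$weight) else 0,
    zero = 0)
  sim[graph$nodes, graph$nodes, drop = FALSE]
}

#' Shortest-path similarity between two conditions
#'
#' The similarity of two conditions is the reciprocal of their weighted
#' shortest-path length (Dijkstra) in the condition network; an unreachable
#' pair has similarity 0. A condition's self-similarity is undefined by the
#' reciprocal transform (zero path length); by default it is set to the
#' maximum attainable inter-node similarity, 1/min(w), keeping the diagonal
#' on the same scale (\code{self_similarity = "zero"} instead sets it to 0).
#'
#' @param graph A [build_condition_graph()] result.
#' @param ci,cj Condition labels (must be nodes of the graph).
#' @param self_similarity \code{"max_sim"} (default) or \code{"zero"}.
#' @return Numeric similarity score.
#' @export
condition_similarity <- function(graph, ci, cj,
                                 self_similarity = c("max_sim", "zero")) {
  if (!ci %in% graph$nodes) stop("condition not in graph: ", ci)
  if (!cj %in% graph$nodes) stop("condition not in graph: ", cj)
  sim <- condition_similarity_matrix(graph, self_similarity)
  sim[ci, cj]
}

#' Trajectory similarity matrix
#'
#' The similarity of two trajectories is the mean of the shortest-path
#' similarities over all pairs of their conditions:
#' sim_traj(i, j) = (1 / (|traj_i| * |traj_j|)) * sum over ci in traj_i,
#' cj in traj_j of sim(ci, cj). The diagonal is computed by the same formula
#' (it includes the self-similarity terms).
#'
#' @param trajs Data frame with columns \code{c1}, \code{c2}, \code{c3}.
#' @param graph A [build_condition_graph()] result covering all trajectory
#'   conditions.
#' @param self_similarity Passed to [condition_similarity_matrix].
#' @return Symmetric non-negative n x n matrix (class
#'   \code{"trajectory_similarity"}), with row/column names
#'   \code{"c1|c2|c3"}.
#' @export
trajectory_similarity_matrix <- function(trajs, graph,
                                         self_similarity = c("max_sim",
                                                             "zero")) {
  n <- nrow(trajs)
  csim <- condition_similarity_matrix(graph, self_similarity)
  cond_idx <- cbind(match(trajs$c1, graph$nodes),
                    match(trajs$c2, graph$nodes),
                    match(trajs$c3, graph$nodes))
  if (anyNA(cond_idx)) stop("trajectory condition(s) missing from graph")
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- mean(csim[cond_idx[i, ], cond_idx[j, ]])
    out[i, j] <- v; out[j, i] <- v
  }
  labels <- paste(trajs$c1, trajs$c2, trajs$c3, sep = "|")
  dimnames(out) <- list(labels, labels)
  class(out) <- c("trajectory_similarity", class(out))
  out
}

#' Export the condition network
#'
#' Writes the weighted edge list
#' (\code{condition_a,condition_b,frequency,weight}) as CSV and, optionally,
#' the graph as GraphML.
#'
#' @param graph A [build_condition_graph()] result.
#' @param edge_list_path CSV path for the edge list (NULL to skip).
#' @param graphml_path GraphML path (NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_condition_graph <- function(graph, edge_list_path = NULL,
                                  graphml_path = NULL) {
  if (!is.null(edge_list_path))
    utils::write.csv(graph$edges, edge_list_path, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  invisible(c(edge_list_path, graphml_path))
}
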