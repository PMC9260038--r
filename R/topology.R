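#' @title Topological measures of a weighted backbone
#' @name topology
#' @description
#' Seven graph-theoretical measures computed on the OMST backbone: global,
#' nodal and local efficiency (information-transfer measures built on
#' weighted shortest paths with edge length `d = 1/w`), and degree,
#' betweenness, eigenvector and pagerank centrality. Degree is binary on the
#' retained edges; eigenvector and pagerank use the edge weights. All nodal
#' functions return a named vector over all nodes.
NULL

backbone_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted shortest path lengths
#'
#' All-pairs shortest path lengths with edge length `d = 1/w` (stronger
#' connections are shorter).
#'
#' @param g An `omst_backbone` or a symmetric nonnegative weight matrix with
#'   zero diagonal.
#' @return Symmetric matrix of path lengths, zero diagonal.
#' @export
shortest_path_lengths <- function(g) {
  w <- as_weight_matrix(g)
  gr <- backbone_graph(w)
  l <- igraph::distances(gr, weights = 1 / igraph::E(gr)$weight)
  if (any(!is.finite(l)))
    stop("graph is disconnected; shortest path lengths undefined")
  dimnames(l) <- dimnames(w)
  l
}

# Mean of 1/L over ordered pairs; tolerates Inf (disconnected pairs -> 0).
efficiency_from_lengths <- function(l) {
  n <- nrow(l)
  inv <- 1 / l
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean of inverse shortest path lengths over all ordered node pairs; equals
#' the average of the nodal efficiencies.
#'
#' @inheritParams shortest_path_lengths
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(g) {
  efficiency_from_lengths(shortest_path_lengths(g))
}

#' Nodal efficiency
#'
#' For each node, the mean of inverse shortest path lengths to every other
#' node.
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector over nodes.
#' @export
nodal_efficiency <- function(g) {
  l <- shortest_path_lengths(g)
  inv <- 1 / l
  diag(inv) <- 0
  rowSums(inv) / (nrow(l) - 1)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (the node itself excluded, edges and weights restricted to the
#' subgraph); zero for nodes with fewer than two neighbors or whose
#' neighborhood has no internal edges. Disconnected neighbor pairs
#' contribute zero (1/Inf).
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector over nodes.
#' @export
local_efficiency <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) next
    sub <- w[nb, nb, drop = FALSE]
    if (all(sub == 0)) next
    gr <- backbone_graph(sub)
    l <- igraph::distances(gr, weights = 1 / igraph::E(gr)$weight)
    out[i] <- efficiency_from_lengths(l)
  }
  out
}

#' Degree centrality
#'
#' Number of retained (nonzero-weight) edges incident to each node; binary
#' on the backbone.
#'
#' @inheritParams shortest_path_lengths
#' @return Named integer vector over nodes.
#' @export
degree_centrality <- function(g) {
  w <- as_weight_matrix(g)
  stats::setNames(as.integer(rowSums(w > 0)), rownames(w))
}

#' Betweenness centrality
#'
#' Fraction of weighted shortest paths (edge length `d = 1/w`) between every
#' unordered pair of other nodes that pass through each node, summed over
#' pairs; un-normalized.
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector over nodes.
#' @export
betweenness_centrality <- function(g) {
  w <- as_weight_matrix(g)
  gr <- backbone_graph(w)
  b <- igraph::betweenness(gr, weights = 1 / igraph::E(gr)$weight,
                           directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), rownames(w))
}

#' Eigenvector centrality
#'
#' Entries of the principal eigenvector of the weighted adjacency matrix,
#' sign-fixed positive and scaled to unit Euclidean norm. The backbone is
#' connected with nonnegative weights, so the Perron vector is unique and
#' strictly positive.
#'
#' @inheritParams shortest_path_lengths
#' @return Named numeric vector over nodes, unit 2-norm.
#' @export
eigenvector_centrality <- function(g) {
  w <- as_weight_matrix(g)
  v <- eigen(w, symmetric = TRUE)$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  stats::setNames(v, rownames(w))
}

#' Pagerank centrality
#'
#' Fixed point of the damped random-walk equation
#' `r(i) = (1-d)/N + d * sum_j w_ij r(j) / s(j)` with node strength
#' `s(j) = sum_k w_jk` (on a unit-weight graph this normalization reduces to
#' the degree), solved by damped iteration. Returned vector sums to 1.
#'
#' @inheritParams shortest_path_lengths
#' @param d Damping factor in (0, 1); default 0.85 (teleport probability
#'   `1 - d = 0.15`).
#' @param tol Convergence tolerance on the max absolute update.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Named numeric vector over nodes summing to 1.
#' @export
pagerank_centrality <- function(g, d = 0.85, tol = 1e-12, max_iter = 10000L) {
  stopifnot(d > 0, d < 1)
  w <- as_weight_matrix(g)
  n <- nrow(w)
  s <- rowSums(w)
  if (any(s == 0)) stop("isolated node: pagerank normalization undefined")
  r <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    r_new <- (1 - d) / n + d * as.vector(w %*% (r / s))
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) return(stats::setNames(r / sum(r), rownames(w)))
  }
  stop(sprintf("pagerank did not converge in %d iterations (residual %.3e)",
               max_iter, delta))
}

#' Compute all seven topological measures
#'
#' Evaluates global efficiency once per graph and the six nodal measures for
#' every node, returning a long-format table.
#'
#' @inheritParams shortest_path_lengths
#' @return data.frame with columns `node` (parcel name or `"global"`),
#'   `measure` (`Eglob`, `Enodal`, `Elocal`, `DC`, `BC`, `EC`, `PC`) and
#'   `value`; `N*6 + 1` rows.
#' @export
compute_topology <- function(g) {
  w <- as_weight_matrix(g)
  l <- shortest_path_lengths(w)
  inv <- 1 / l
  diag(inv) <- 0
  enodal <- rowSums(inv) / (nrow(l) - 1)
  eglob <- mean(enodal)
  nodal <- list(Enodal = enodal,
                Elocal = local_efficiency(w),
                DC = as.numeric(degree_centrality(w)),
                BC = betweenness_centrality(w),
                EC = eigenvector_centrality(w),
                PC = pagerank_centrality(w))
  nodes <- rownames(w)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(w)))
  out <- do.call(rbind, lapply(names(nodal), function(m)
    data.frame(node = nodes, measure = m, value = as.numeric(nodal[[m]]),
               stringsAsFactors = FALSE)))
  rbind(data.frame(node = "global", measure = "Eglob", value = eglob,
                   stringsAsFactors = FALSE),
        out)
}
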