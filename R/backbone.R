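#' Absolute-value weighted graph from a connectivity matrix
#'
#' Takes entrywise absolute values of a (possibly signed) connectivity
#' matrix and zeroes the diagonal, yielding the nonnegative weighted graph
#' that OMST thresholding operates on.
#'
#' @param m Symmetric connectivity matrix (entries in \[-1, 1\]).
#' @return Symmetric nonnegative matrix with zero diagonal, dimnames kept.
#' @export
absolutize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-10) stop("connectivity matrix must be symmetric")
  out <- abs(m)
  diag(out) <- 0
  out
}

# Upper-triangle edge list of a weight matrix: columns i, j (i < j), w.
edge_table <- function(w, drop_zero = TRUE) {
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  e <- data.frame(i = idx[, 1L], j = idx[, 2L], w = w[idx])
  if (drop_zero) e <- e[e$w > 0, , drop = FALSE]
  e[order(e$i, e$j), , drop = FALSE]
}

# Kruskal minimum spanning tree on distances d = 1/w with lexicographic
# tie-breaking by (d, i, j). Returns row indices of `edges` in the tree, or
# NULL when the available edges do not span all n nodes. Hand-written
# (rather than igraph::mst) because the tie rule must be deterministic.
kruskal_mst <- function(edges, n) {
  if (nrow(edges) < n - 1L) return(NULL)
  ord <- order(1 / edges$w, edges$i, edges$j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- integer(0)
  for (k in ord) {
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      take <- c(take, k)
      if (length(take) == n - 1L) break
    }
  }
  if (length(take) < n - 1L) return(NULL)
  sort(take)
}

# Global efficiency (mean of 1/L over ordered pairs) of a weight matrix,
# with path lengths d = 1/w after dividing weights by `wmax`.
eglob_weighted <- function(w, wmax = max(w)) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  l <- igraph::distances(g, weights = wmax / igraph::E(g)$weight)
  inv <- 1 / l
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global cost efficiency of a backbone relative to the full graph
#'
#' The selection functional of OMST thresholding: the global efficiency of
#' the retained graph (path lengths `d = 1/w` with weights normalized by the
#' maximum weight of the *original* graph, so the value is scale-free) minus
#' its cost, the fraction of total edge weight retained.
#'
#' @param backbone Weight matrix of the retained edges (or an
#'   `omst_backbone` object).
#' @param original Weight matrix of the full graph the backbone came from.
#' @return Scalar global cost efficiency.
#' @export
global_cost_efficiency <- function(backbone, original) {
  wb <- as_weight_matrix(backbone)
  stopifnot(is.matrix(original), all(dim(wb) == dim(original)))
  total <- sum(original[upper.tri(original)])
  if (total <= 0) stop("original graph has zero total weight")
  if (all(wb[upper.tri(wb)] == 0)) stop("backbone has no edges")
  eff <- eglob_weighted(wb, wmax = max(original))
  cost <- sum(wb[upper.tri(wb)]) / total
  eff - cost
}

#' OMST thresholding of a weighted graph
#'
#' Iteratively extracts maximum-weight spanning trees (minimum spanning
#' trees on distances `d = 1/w`), each edge-disjoint ("orthogonal") to all
#' previous ones, and records after each round the global cost efficiency
#' (GCE) of the union so far. The returned backbone is the union of the
#' first `m*` trees where `m*` maximizes GCE. Rounds stop when no full
#' spanning tree can be formed from the remaining edges, when GCE has
#' decreased for two consecutive rounds, or at `max_trees` rounds
#' (default `floor((N-1)/2)`, at least 1). Tie-breaking among equal-weight
#' edges is lexicographic by node order, so the result is deterministic.
#'
#' @param g Symmetric nonnegative weight matrix with zero diagonal (see
#'   [absolutize()]); must be connected on its nonzero edges.
#' @param max_trees Cap on the number of rounds.
#' @return An object of class `omst_backbone`: a list with `weights` (the
#'   retained-edge weight matrix), `omst_count`, `cost`, `gce` (GCE at the
#'   selected round), `gce_curve`, `cost_curve`, and `trees` (list of
#'   per-round edge index matrices).
#' @export
omst_backbone <- function(g, max_trees = NULL) {
  stopifnot(is.matrix(g), nrow(g) == ncol(g), nrow(g) >= 2L)
  if (any(g < 0)) stop("weights must be nonnegative; apply absolutize() first")
  if (any(diag(g) != 0)) stop("self-loops are not allowed (nonzero diagonal)")
  n <- nrow(g)
  labels <- rownames(g)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (is.null(max_trees)) max_trees <- max(1L, (n - 1L) %/% 2L)
  edges <- edge_table(g)
  if (nrow(edges) < n - 1L)
    stop("fewer than N-1 nonzero edges; graph cannot be connected")

  total_w <- sum(edges$w)
  wmax <- max(edges$w)
  avail <- rep(TRUE, nrow(edges))
  union_w <- matrix(0, n, n, dimnames = list(labels, labels))
  trees <- list()
  gce_curve <- numeric(0)
  cost_curve <- numeric(0)
  unions <- list()

  for (m in seq_len(max_trees)) {
    take <- kruskal_mst(edges[avail, , drop = FALSE], n)
    if (is.null(take)) {
      if (m == 1L) stop("graph is disconnected; OMST undefined")
      break
    }
    rows <- which(avail)[take]
    avail[rows] <- FALSE
    tr <- edges[rows, , drop = FALSE]
    trees[[m]] <- as.matrix(tr[, c("i", "j")])
    for (k in seq_len(nrow(tr)))
      union_w[tr$i[k], tr$j[k]] <- union_w[tr$j[k], tr$i[k]] <- tr$w[k]
    cost_curve[m] <- sum(union_w[upper.tri(union_w)]) / total_w
    gce_curve[m] <- eglob_weighted(union_w, wmax = wmax) - cost_curve[m]
    unions[[m]] <- union_w
    if (m >= 3L && gce_curve[m] < gce_curve[m - 1L] &&
        gce_curve[m - 1L] < gce_curve[m - 2L]) break
  }

  m_star <- which.max(gce_curve)
  structure(list(weights = unions[[m_star]],
                 labels = labels,
                 omst_count = m_star,
                 cost = cost_curve[m_star],
                 gce = gce_curve[m_star],
                 gce_curve = gce_curve,
                 cost_curve = cost_curve,
                 trees = trees[seq_len(m_star)]),
            class = "omst_backbone")
}

#' @export
print.omst_backbone <- function(x, ...) {
  cat("OMST backbone:", length(x$labels), "nodes,",
      sum(x$weights[upper.tri(x$weights)] > 0), "edges,",
      x$omst_count, "orthogonal tree(s)\n")
  cat(sprintf("cost = %.4f, GCE = %.4f\n", x$cost, x$gce))
  invisible(x)
}

# Coerce a backbone object or plain matrix to its weight matrix.
as_weight_matrix <- function(x) {
  if (inherits(x, "omst_backbone")) return(x$weights)
  stopifnot(is.matrix(x))
  x
}
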