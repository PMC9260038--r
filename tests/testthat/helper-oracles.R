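# Independent brute-force oracles used to verify the graph machinery.
# These deliberately share no code with the package implementation.

# All-pairs shortest paths by Floyd-Warshall on direct distances d = 1/w.
oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Enumerate all simple paths between two nodes (adjacency on w > 0).
all_simple_paths_between <- function(w, from, to) {
  n <- nrow(w)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(w[last, ] > 0))
      if (!nxt %in% path) walk(c(path, nxt))
  }
  walk(from)
  out
}

# Betweenness by exhaustive enumeration of minimal-length simple paths.
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (h in seq_len(n - 1L)) {
    for (j in seq.int(h + 1L, n)) {
      paths <- all_simple_paths_between(w, h, j)
      lens <- vapply(paths, function(p)
        sum(1 / w[cbind(p[-length(p)], p[-1L])]), numeric(1))
      shortest <- paths[lens <= min(lens) + tol]
      for (i in setdiff(seq_len(n), c(h, j))) {
        through <- sum(vapply(shortest, function(p) i %in% p, logical(1)))
        bc[i] <- bc[i] + through / length(shortest)
      }
    }
  }
  bc
}

# Principal eigenvector by shifted power iteration on the weight matrix.
# The diagonal shift keeps the dominant eigenvalue simple and positive even
# for near-bipartite graphs whose most negative eigenvalue rivals the
# largest; it leaves the eigenvectors unchanged.
oracle_power_iteration <- function(w, iters = 100000L) {
  shift <- max(rowSums(w))
  a <- w + diag(shift, nrow(w))
  v <- rep(1, nrow(w))
  for (k in seq_len(iters)) {
    v_new <- as.vector(a %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < 1e-14) return(v_new)
    v <- v_new
  }
  v
}

# Pagerank by direct linear solve of (I - d W S^-1) r = ((1-d)/n) 1.
oracle_pagerank_solve <- function(w, d = 0.85) {
  n <- nrow(w)
  s <- rowSums(w)
  a <- diag(n) - d * w %*% diag(1 / s)
  r <- solve(a, rep((1 - d) / n, n))
  as.vector(r / sum(r))
}

# Global efficiency (ordered-pair mean of 1/L) from a weight matrix with
# weights divided by wmax, via the Floyd-Warshall oracle.
oracle_eglob <- function(w, wmax = max(w)) {
  l <- oracle_floyd_warshall(w / wmax)
  inv <- 1 / l
  diag(inv) <- 0
  sum(inv) / (nrow(w) * (nrow(w) - 1))
}

# Enumerate every spanning tree of the graph on `edges` (data.frame i,j,w
# over n nodes) and return the one minimizing total distance sum(1/w).
oracle_min_spanning_tree <- function(edges, n) {
  m <- nrow(edges)
  if (m < n - 1L) return(NULL)
  combos <- utils::combn(m, n - 1L)
  best <- NULL
  best_len <- Inf
  for (c_i in seq_len(ncol(combos))) {
    rows <- combos[, c_i]
    # connected with n-1 edges <=> spanning tree
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in rows) {
      ri <- find(edges$i[k]); rj <- find(edges$j[k])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (!ok) next
    len <- sum(1 / edges$w[rows])
    if (len < best_len - 1e-12) { best_len <- len; best <- rows }
  }
  best
}

# Full OMST scheme by spanning-tree enumeration: at each round take the
# minimum-distance spanning tree of the remaining edges, track the global
# cost efficiency of the union, and return the union maximizing it.
oracle_omst <- function(w, max_trees = max(1L, (nrow(w) - 1L) %/% 2L)) {
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], w = w[idx])
  total_w <- sum(edges$w)
  wmax <- max(edges$w)
  avail <- rep(TRUE, nrow(edges))
  union_w <- matrix(0, n, n)
  gce <- numeric(0)
  unions <- list()
  for (m in seq_len(max_trees)) {
    rows <- oracle_min_spanning_tree(edges[avail, , drop = FALSE], n)
    if (is.null(rows)) break
    rows <- which(avail)[rows]
    avail[rows] <- FALSE
    for (k in rows)
      union_w[edges$i[k], edges$j[k]] <- union_w[edges$j[k], edges$i[k]] <-
        edges$w[k]
    cost <- sum(union_w[upper.tri(union_w)]) / total_w
    gce[m] <- oracle_eglob(union_w, wmax) - cost
    unions[[m]] <- union_w
    if (m >= 3L && gce[m] < gce[m - 1L] && gce[m - 1L] < gce[m - 2L]) break
  }
  list(weights = unions[[which.max(gce)]], omst_count = which.max(gce),
       gce_curve = gce)
}

# Random connected weighted graph: a random spanning tree plus extra edges,
# weights uniform on [0.2, 1] (distinct with probability 1).
random_backbone_matrix <- function(n, extra = n, labels = TRUE) {
  w <- matrix(0, n, n)
  perm <- sample(n)
  for (k in 2:n) {
    a <- perm[k]
    b <- perm[sample(k - 1L, 1L)]
    w[a, b] <- w[b, a] <- stats::runif(1, 0.2, 1)
  }
  free <- which(upper.tri(w) & w == 0)
  if (extra > 0 && length(free) > 0) {
    pick <- sample(free, min(extra, length(free)))
    w[pick] <- stats::runif(length(pick), 0.2, 1)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  if (labels) dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  w
}

# Complete graph with distinct random weights.
random_complete_matrix <- function(n, labels = TRUE) {
  w <- matrix(0, n, n)
  m <- n * (n - 1L) / 2L
  w[upper.tri(w)] <- sample(seq(0.1, 1, length.out = m * 10), m)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  if (labels) dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  w
}
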