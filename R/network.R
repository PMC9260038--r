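#' @title Morphological similarity and functional connectivity matrices
#' @name network_construction
#' @description
#' Construction of the two kinds of individual brain networks analyzed by
#' the package: morphological similarity networks, whose edges are Pearson
#' correlations between two parcels' frequency histograms of a vertex-wise
#' morphometric measure, and functional connectivity networks, whose edges
#' are Pearson correlations between parcel-average BOLD time series (static
#' over the whole scan or dynamic over sliding windows).
NULL

# Uniform histogram counts over [lo, hi]: left-closed bins, rightmost bin
# closed so values equal to the pooled maximum are not lost.
uniform_bin_counts <- function(x, lo, hi, bins) {
  breaks <- seq(lo, hi, length.out = bins + 1L)
  graphics::hist(x, breaks = breaks, right = FALSE, include.lowest = TRUE,
                 plot = FALSE)$counts
}

#' Shared histogram bin edges for a parcel pair
#'
#' The uniform bin edges that [pair_histogram_similarity()] uses: `bins`
#' equal-width bins spanning the pooled range of both parcels' values (for
#' example, a pooled volume range of 5.4 to 61.2 mm^3 with 30 bins gives a
#' bin width of 1.68).
#'
#' @inheritParams pair_histogram_similarity
#' @return Numeric vector of `bins + 1` edges.
#' @export
similarity_bin_edges <- function(values_a, values_b, bins = 30L) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1, bins >= 2)
  pooled <- range(c(values_a, values_b))
  if (diff(pooled) <= 0)
    stop("degenerate pair: pooled value range is zero, histogram undefined")
  seq(pooled[1L], pooled[2L], length.out = bins + 1L)
}

#' Histogram-distribution similarity of two parcels
#'
#' Bins the two value lists into `bins` uniform bins spanning the *pooled*
#' range of both parcels (one shared set of bin edges), and returns the
#' Pearson correlation of the two frequency vectors. This is the edge weight
#' of the morphological similarity network.
#'
#' @param values_a,values_b Numeric vectors of vertex-wise values (e.g.
#'   cortical volume in mm^3) for the two parcels.
#' @param bins Number of uniform bins (>= 2); the scan over bin numbers is
#'   the spatial-scale axis of the analysis.
#' @return Pearson correlation of the two frequency vectors, in \[-1, 1\];
#'   `NA` with a warning if either frequency vector has zero variance.
#' @export
#' @examples
#' pair_histogram_similarity(c(1, 1, 2), c(2, 3, 3), bins = 2)  # -1
pair_histogram_similarity <- function(values_a, values_b, bins = 30L) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1, bins >= 2)
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("vertex values must be finite")
  pooled <- range(c(values_a, values_b))
  if (diff(pooled) <= 0)
    stop("degenerate pair: pooled value range is zero, histogram undefined")
  fa <- uniform_bin_counts(values_a, pooled[1L], pooled[2L], bins)
  fb <- uniform_bin_counts(values_b, pooled[1L], pooled[2L], bins)
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    warning("zero-variance frequency vector; similarity undefined (NA)")
    return(NA_real_)
  }
  stats::cor(fa, fb)
}

#' Build a morphological similarity network
#'
#' Computes [pair_histogram_similarity()] for every pair of parcels in a
#' vertex-value table and assembles the symmetric similarity matrix
#' (diagonal 1).
#'
#' @param table Named list mapping parcel name to a numeric vector of
#'   vertex-wise values (a `VertexValueTable` for one subject and measure).
#' @param bins Number of histogram bins.
#' @return Symmetric N x N numeric matrix with parcel names as dimnames and
#'   attribute `bins`; entries in \[-1, 1\], diagonal 1.
#' @export
build_morph_network <- function(table, bins = 30L) {
  stopifnot(is.list(table), length(table) >= 2L,
            !is.null(names(table)), !anyDuplicated(names(table)))
  n <- length(table)
  m <- diag(1, n)
  dimnames(m) <- list(names(table), names(table))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- pair_histogram_similarity(table[[i]], table[[j]], bins)
      m[i, j] <- m[j, i] <- r
    }
  }
  attr(m, "bins") <- as.integer(bins)
  m
}

#' Sweep the histogram bin number to obtain networks at several spatial scales
#'
#' Rebuilds the morphological similarity network over a range of bin numbers
#' (default 24 to 36 in steps of 2, i.e. 7 networks), the spatial-scale
#' counterpart of the temporal sliding-window sweep.
#'
#' @inheritParams build_morph_network
#' @param b_min,b_max,step Bin-number range and step.
#' @return Named list of similarity matrices, one per bin setting; names are
#'   the bin numbers.
#' @export
sweep_bin_numbers <- function(table, b_min = 24L, b_max = 36L, step = 2L) {
  stopifnot(b_min <= b_max, step >= 1, b_min >= 2)
  bins <- seq.int(b_min, b_max, by = step)
  out <- lapply(bins, function(b) build_morph_network(table, b))
  names(out) <- bins
  out
}

#' Static functional connectivity
#'
#' Pearson correlation matrix of parcel-average BOLD time series over the
#' full scan.
#'
#' @param ts Numeric matrix, parcels x time points, with parcel names as
#'   rownames.
#' @return Symmetric correlation matrix (diagonal 1).
#' @export
static_fc <- function(ts) {
  stopifnot(is.matrix(ts), ncol(ts) >= 3L)
  v <- apply(ts, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance time series for parcel(s): ",
         paste(rownames(ts)[v == 0], collapse = ", "))
  m <- stats::cor(t(ts))
  diag(m) <- 1
  m
}

#' Sliding-window dynamic functional connectivity
#'
#' Segments the time series into windows of `window` TRs shifting by `step`
#' TRs and computes a correlation matrix in each window. With the defaults
#' (235 time points, window 50, step 1) this yields 186 dynamic networks.
#'
#' @inheritParams static_fc
#' @param window Window length in TRs (>= 3).
#' @param step Shift between consecutive windows in TRs.
#' @return List of correlation matrices, one per window, named by the
#'   1-based start index of the window.
#' @export
sliding_window_fc <- function(ts, window = 50L, step = 1L) {
  stopifnot(is.matrix(ts), window >= 3L, step >= 1L)
  tt <- ncol(ts)
  if (window > tt)
    stop("window length (", window, ") exceeds the number of time points (",
         tt, ")")
  starts <- seq.int(1L, tt - window + 1L, by = step)
  out <- lapply(starts, function(s)
    static_fc(ts[, s:(s + window - 1L), drop = FALSE]))
  names(out) <- starts
  out
}
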