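#' Cortical parcel roster retained for network analysis
#'
#' Returns the 30 parcels of the Yeo 51-parcel cortical parcellation that
#' survive the vertex-count filter (at least 50 surface vertices), together
#' with hemisphere, Yeo-7 network membership and vertex count. These are the
#' nodes of every network built by the package.
#'
#' @return A data.frame with columns `name`, `hemisphere` (`"LH"`/`"RH"`),
#'   `network` (one of the seven Yeo networks) and `vertex_count`.
#' @seealso [full_parcellation()] for the 51-parcel input roster,
#'   [filter_parcels()] for the filter itself.
#' @export
#' @examples
#' p <- retained_parcels()
#' nrow(p)            # 30
#' range(p$vertex_count)
retained_parcels <- function() {
  lh <- data.frame(
    name = c("Vis", "SomMot", "DorsAttn_Post", "DorsAttn_FEF",
             "SalVentAttn_ParOper", "SalVentAttn_FrOper", "SalVentAttn_Med",
             "Limbic_TempPole", "Cont_Par", "Cont_PFCl", "Default_Par",
             "Default_Temp", "Default_PFC", "Default_PCC"),
    vertex_count = c(1213L, 1590L, 616L, 97L, 130L, 331L, 216L, 164L, 151L,
                     291L, 263L, 311L, 768L, 275L),
    hemisphere = "LH", stringsAsFactors = FALSE)
  rh <- data.frame(
    name = c("Vis", "SomMot", "DorsAttn_Post", "DorsAttn_FEF",
             "DorsAttn_PrCv", "SalVentAttn_TempOccPar", "SalVentAttn_FrOper",
             "SalVentAttn_Med", "Limbic_TempPole", "Cont_Par", "Cont_PFCl",
             "Default_Par", "Default_Temp", "Default_PFCv", "Default_PFCm",
             "Default_PCC"),
    vertex_count = c(1262L, 1612L, 589L, 98L, 50L, 208L, 313L, 242L, 136L,
                     167L, 537L, 183L, 246L, 60L, 453L, 225L),
    hemisphere = "RH", stringsAsFactors = FALSE)
  out <- rbind(lh, rh)
  out$network <- vapply(strsplit(out$name, "_", fixed = TRUE),
                        function(x) x[[1L]], character(1))
  out$name <- paste(out$hemisphere, out$name, sep = "_")
  out[, c("name", "hemisphere", "network", "vertex_count")]
}

#' Full 51-parcel input roster (retained parcels plus synthetic small parcels)
#'
#' The source parcellation has 51 parcels but only the 30 with at least 50
#' vertices are analyzed; the sub-threshold parcels are not enumerated in the
#' study's tables. This function appends 21 *synthetic* small parcels
#' (vertex counts drawn deterministically below 50) to [retained_parcels()]
#' so that the parcel filter can be exercised on a full-size roster.
#'
#' @param seed Integer seed fixing the synthetic small-parcel vertex counts.
#' @return A data.frame in the same format as [retained_parcels()] with 51
#'   rows; the 21 appended rows are named `*_small<i>` and all have
#'   `vertex_count < 50`.
#' @export
full_parcellation <- function(seed = 1L) {
  keep <- retained_parcels()
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont",
            "Default")
  n_extra <- 51L - nrow(keep)
  counts <- with_local_seed(seed, sample(5:49, n_extra, replace = TRUE))
  extra <- data.frame(
    name = paste0(rep(c("LH", "RH"), length.out = n_extra), "_",
                  rep(nets, length.out = n_extra), "_small", seq_len(n_extra)),
    hemisphere = rep(c("LH", "RH"), length.out = n_extra),
    network = rep(nets, length.out = n_extra),
    vertex_count = as.integer(counts),
    stringsAsFactors = FALSE)
  rbind(keep, extra)
}

#' Filter parcels by vertex count
#'
#' Drops parcels whose surface vertex count falls below `threshold`,
#' preserving order. The study's rule excludes parcels with fewer than 50
#' vertices, so a parcel with exactly 50 vertices is retained.
#'
#' @param parcels data.frame with at least `name` and `vertex_count` columns.
#' @param threshold Minimum vertex count to keep (default 50).
#' @return The retained rows of `parcels`, order preserved.
#' @export
#' @examples
#' nrow(filter_parcels(full_parcellation()))  # 30
filter_parcels <- function(parcels, threshold = 50L) {
  stopifnot(is.data.frame(parcels), threshold >= 1,
            all(c("name", "vertex_count") %in% names(parcels)))
  if (any(parcels$vertex_count < 1))
    stop("vertex_count must be >= 1 for every parcel")
  out <- parcels[parcels$vertex_count >= threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no parcel reaches the vertex-count threshold; network undefined")
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
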