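#' @title Delimited-text readers and writers
#' @name braintopo_io
#' @description
#' All on-disk formats are tab-separated text: per-subject vertex-value
#' tables (`parcel`, `value`), per-subject time-series matrices (`parcel`
#' column plus one column per time point), the behavior table, square
#' connectivity matrices with parcel labels on both axes, and weighted edge
#' lists. Numeric values are written with 17 significant digits so a
#' write/read round trip reproduces them exactly.
NULL

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a synthetic cohort to disk as fixtures
#'
#' Writes `behavior.tsv`, one morphometry table per subject and measure
#' under `morph/`, one time-series matrix per subject under `bold/`, and a
#' JSON manifest recording the generator configuration (including the
#' seed), so the identical cohort can be regenerated or re-read.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bt_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  mdir <- file.path(dir, "morph"); dir.create(mdir, showWarnings = FALSE)
  bdir <- file.path(dir, "bold"); dir.create(bdir, showWarnings = FALSE)
  for (s in names(cohort$morphometry)) {
    for (m in names(cohort$morphometry[[s]])) {
      tab <- cohort$morphometry[[s]][[m]]
      df <- data.frame(parcel = rep(names(tab), lengths(tab)),
                       value = unlist(tab, use.names = FALSE))
      write_tsv(df, file.path(mdir, paste0(s, "_", m, ".tsv")))
    }
  }
  for (s in names(cohort$bold)) {
    x <- cohort$bold[[s]]
    df <- data.frame(parcel = rownames(x))
    vals <- as.data.frame(x)
    names(vals) <- paste0("t", seq_len(ncol(x)))
    write_tsv(cbind(df, vals), file.path(bdir, paste0(s, ".tsv")))
  }
  cfg <- cohort$config
  manifest <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                   n_timepoints = cfg$n_timepoints,
                   tr_seconds = cfg$tr_seconds, band = cfg$band,
                   bold_coupling = cfg$bold_coupling,
                   bold_states = cfg$bold_states,
                   bold_state_couplings = cfg$bold_state_couplings,
                   parcels = cfg$parcels,
                   morph_effects = cfg$morph_effects,
                   bold_effects = cfg$bold_effects,
                   subjects = names(cohort$bold))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a behavior table
#' @param path Path to a `behavior.tsv` written by [write_fixtures()].
#' @return data.frame.
#' @export
read_behavior <- function(path) read_tsv(path)

#' Read a vertex-value table
#'
#' @param path Path to a two-column (`parcel`, `value`) TSV.
#' @return Named list mapping parcel name to its numeric vector of vertex
#'   values, in file order.
#' @export
read_morphometry <- function(path) {
  df <- read_tsv(path)
  split(df$value, factor(df$parcel, levels = unique(df$parcel)))
}

#' Read a parcel time-series matrix
#'
#' @param path Path to a TSV with a `parcel` column and one column per time
#'   point.
#' @return Numeric matrix, parcels x time points, parcel names as rownames.
#' @export
read_timeseries <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$parcel, NULL)
  m
}

#' Write / read a square connectivity matrix
#'
#' The on-disk format is a TSV with parcel labels as the first column and
#' as the header row.
#'
#' @param m Square matrix with dimnames.
#' @param path File path.
#' @return `read_connectivity` returns the matrix; `write_connectivity`
#'   returns `path` invisibly.
#' @export
write_connectivity <- function(m, path) {
  df <- data.frame(parcel = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$parcel
  m
}

#' Weighted edge list of a connectivity matrix or backbone
#'
#' @param m Square symmetric matrix (or `omst_backbone`).
#' @param drop_zero Drop zero-weight pairs (default TRUE).
#' @return data.frame with `node_a`, `node_b`, `weight` (upper triangle).
#' @export
matrix_edge_list <- function(m, drop_zero = TRUE) {
  w <- as_weight_matrix(m)
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(w)))
  e <- edge_table(w, drop_zero = drop_zero)
  data.frame(node_a = labels[e$i], node_b = labels[e$j], weight = e$w,
             stringsAsFactors = FALSE)
}

#' Export an OMST backbone as an edge list with a JSON sidecar
#'
#' Writes `<path>.tsv` (weighted edge list) and `<path>.json` (number of
#' orthogonal trees, cost, and the full GCE curve).
#'
#' @param backbone An [omst_backbone()] result.
#' @param path Path stem (without extension).
#' @return The TSV path, invisibly.
#' @export
write_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "omst_backbone"))
  write_tsv(matrix_edge_list(backbone), paste0(path, ".tsv"))
  jsonlite::write_json(list(omst_count = backbone$omst_count,
                            cost = backbone$cost, gce = backbone$gce,
                            gce_curve = backbone$gce_curve,
                            cost_curve = backbone$cost_curve),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".tsv"))
}

#' Read a cohort back from fixtures
#'
#' Reconstructs the in-memory cohort (behavior, morphometry, bold) from a
#' directory written by [write_fixtures()].
#'
#' @param dir Fixture directory.
#' @return List with `behavior`, `morphometry`, `bold`, `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  behavior <- read_behavior(file.path(dir, "behavior.tsv"))
  subjects <- behavior$subject
  morph_files <- list.files(file.path(dir, "morph"), full.names = TRUE)
  morph <- lapply(subjects, function(s) {
    mine <- morph_files[startsWith(basename(morph_files), paste0(s, "_"))]
    meas <- sub("\\.tsv$", "", sub(paste0("^", s, "_"), "", basename(mine)))
    stats::setNames(lapply(mine, read_morphometry), meas)
  })
  names(morph) <- subjects
  bold <- lapply(subjects, function(s)
    read_timeseries(file.path(dir, "bold", paste0(s, ".tsv"))))
  names(bold) <- subjects
  list(behavior = behavior, morphometry = morph, bold = bold,
       manifest = manifest)
}
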