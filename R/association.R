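#' Covariate-adjusted partial correlation
#'
#' Residualizes the outcome (an anxiety score) and the predictor (a
#' topological statistic) on the covariates plus an intercept by least
#' squares, then correlates the residuals. The resulting partial r is
#' identical to the one implied by the GLM in which the predictor enters
#' alongside the covariates, and its t statistic uses
#' `df = n - k - 2` with `k` covariates.
#'
#' @param outcome,predictor Numeric vectors of equal length, no missing
#'   values.
#' @param covariates Optional numeric matrix/data.frame of covariate
#'   columns; with none, the partial correlation reduces to the plain
#'   Pearson correlation.
#' @return One-row data.frame with `r`, `t`, `p` (two-sided), `df`, `n`.
#'   A predictor that is (numerically) an exact linear combination of the
#'   covariates is degenerate: `r` is `NA` with a warning.
#' @export
partial_correlation <- function(outcome, predictor, covariates = NULL) {
  n <- length(outcome)
  stopifnot(length(predictor) == n)
  if (is.null(covariates)) {
    x_cov <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    x_cov <- as.matrix(covariates)
    stopifnot(nrow(x_cov) == n)
  }
  k <- ncol(x_cov)
  if (anyNA(outcome) || anyNA(predictor) || anyNA(x_cov))
    stop("missing values are not allowed")
  if (n <= k + 2L)
    stop("need n > number of covariates + 2 (n = ", n, ", k = ", k, ")")
  design <- cbind(`(Intercept)` = 1, x_cov)
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    bad <- colnames(design)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(design))]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res_y <- qr.resid(qr_x, outcome)
  res_x <- qr.resid(qr_x, predictor)
  df <- n - k - 2L
  if (stats::var(res_x) < .Machine$double.eps * max(1, stats::var(predictor))) {
    warning("predictor has no residual variance after covariate adjustment; ",
            "partial correlation undefined")
    return(data.frame(r = NA_real_, t = NA_real_, p = NA_real_, df = df, n = n))
  }
  r <- stats::cor(res_y, res_x)
  t <- r * sqrt(df) / sqrt(1 - r^2)
  data.frame(r = r, t = t, p = 2 * stats::pt(-abs(t), df), df = df, n = n)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH adjustment over one family of tests (in this analysis, the 30
#' parcel-level tests of a single measure/statistic/anxiety-dimension
#' combination), flagging adjusted p-values below `q_level`.
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return List with `q` (BH-adjusted p-values) and `significant` (logical,
#'   `q < q_level`).
#' @export
fdr_correct <- function(p, q_level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q < q_level)
}

covariate_sets <- list(
  structural = c("age", "gender", "education", "ICV"),
  functional = c("age", "gender", "education", "mcBBR", "meanFD"))

morph_total_column <- c(volume = "total_volume", area = "total_area",
                        thickness = "mean_thickness")

#' Parcel-family association analysis
#'
#' Runs the covariate-adjusted partial correlation of one topological
#' statistic against one anxiety dimension for every parcel, then applies
#' BH-FDR over the parcel family. The covariate set follows the arm:
#' structural networks adjust for age, gender, education, intracranial
#' volume and the measure-specific morphometric total (total volume, total
#' area or mean thickness); functional networks adjust for age, gender,
#' education, the boundary-based registration cost (mcBBR) and mean
#' framewise displacement (meanFD).
#'
#' @param stat_matrix Subjects x parcels numeric matrix of the statistic
#'   (rows aligned with `behavior` rows; parcel names as colnames).
#' @param behavior Behavior/covariate data.frame (see
#'   [generate_behavior()]); must contain the outcome and covariate columns.
#' @param outcome `"state_anxiety"` or `"trait_anxiety"`.
#' @param arm `"structural"` or `"functional"`.
#' @param morph_measure For the structural arm, which morphometric measure
#'   the statistic came from (`"volume"`, `"area"` or `"thickness"`); picks
#'   the matching total covariate.
#' @param q_level FDR level for the family (default 0.05).
#' @param measure,statistic Optional labels copied into the output.
#' @return data.frame sorted by raw p with columns `arm`, `measure`,
#'   `statistic`, `node`, `outcome`, `r`, `t`, `p`, `df`, `n`, `q`,
#'   `significant`.
#' @export
run_family <- function(stat_matrix, behavior,
                       outcome = c("state_anxiety", "trait_anxiety"),
                       arm = c("structural", "functional"),
                       morph_measure = NULL, q_level = 0.05,
                       measure = NA_character_, statistic = NA_character_) {
  outcome <- match.arg(outcome)
  arm <- match.arg(arm)
  stat_matrix <- as.matrix(stat_matrix)
  stopifnot(nrow(stat_matrix) == nrow(behavior))
  covs <- covariate_sets[[arm]]
  if (arm == "structural") {
    if (is.null(morph_measure) ||
        !morph_measure %in% names(morph_total_column))
      stop("structural arm needs morph_measure in ",
           paste(names(morph_total_column), collapse = "/"))
    covs <- c(covs, morph_total_column[[morph_measure]])
  }
  missing_cols <- setdiff(c(outcome, covs), names(behavior))
  if (length(missing_cols))
    stop("behavior table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  cov_mat <- as.matrix(behavior[, covs, drop = FALSE])
  y <- behavior[[outcome]]
  res <- do.call(rbind, lapply(colnames(stat_matrix), function(node) {
    out <- partial_correlation(y, stat_matrix[, node], cov_mat)
    cbind(data.frame(arm = arm, measure = measure, statistic = statistic,
                     node = node, outcome = outcome,
                     stringsAsFactors = FALSE), out)
  }))
  fdr <- fdr_correct(res$p, q_level)
  res$q <- fdr$q
  res$significant <- fdr$significant
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
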