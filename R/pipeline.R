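#' Apply subject-level quality-control exclusions
#'
#' Removes subjects flagged as having no MRI or a failed mental-health
#' interview, then subjects whose boundary-based registration cost exceeds
#' 0.65 (strictly greater; a subject at exactly 0.65 is retained), and
#' reports counts per reason. With the study's flag counts (67 subjects:
#' 1 without MRI, 1 failed interview, 5 with mcBBR > 0.65) this retains 60.
#'
#' @param cohort_log data.frame with columns `subject`, `no_mri` (logical),
#'   `failed_interview` (logical), `mcBBR` (numeric; may be `NA` for
#'   subjects without MRI).
#' @param mcbbr_max Exclusion bound on mcBBR (default 0.65).
#' @return List with `retained` (character vector of subject ids) and
#'   `counts` (named: `no_mri`, `failed_interview`, `mcbbr`, `retained`).
#' @export
apply_subject_exclusions <- function(cohort_log, mcbbr_max = 0.65) {
  stopifnot(all(c("subject", "no_mri", "failed_interview", "mcBBR") %in%
                  names(cohort_log)))
  log <- cohort_log
  n_no_mri <- sum(log$no_mri)
  log <- log[!log$no_mri, , drop = FALSE]
  n_interview <- sum(log$failed_interview)
  log <- log[!log$failed_interview, , drop = FALSE]
  bad_bbr <- !is.na(log$mcBBR) & log$mcBBR > mcbbr_max
  n_bbr <- sum(bad_bbr)
  log <- log[!bad_bbr, , drop = FALSE]
  list(retained = log$subject,
       counts = c(no_mri = n_no_mri, failed_interview = n_interview,
                  mcbbr = n_bbr, retained = nrow(log)))
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. The defaults are the
#' study settings: morphological similarity with bin numbers 24-36 in steps
#' of 2 (single-network analysis at 30 bins), sliding windows of 50 TRs with
#' step 1, 20-bin histograms for the window distributions, and BH-FDR at
#' q < 0.05 over the 30-parcel family.
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `input_dir` points to fixtures on disk.
#' @param input_dir Optional directory of fixtures written by
#'   [write_fixtures()].
#' @param arm `"structural"`, `"functional"` or `"both"`.
#' @param morph_measures Morphometric measures for the structural arm.
#' @param bin_min,bin_max,bin_step Spatial bin-number sweep.
#' @param single_bins Bin number of the single-scale structural network.
#' @param window_length,window_step Sliding-window settings in TRs.
#' @param histogram_bins Bin count of the window-distribution histograms.
#' @param q_level FDR level.
#' @param associations Run the association stage (needs enough subjects).
#' @param out_dir Optional output directory for result TSVs and a manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            arm = c("both", "structural", "functional"),
                            morph_measures = c("volume", "area", "thickness"),
                            bin_min = 24L, bin_max = 36L, bin_step = 2L,
                            single_bins = 30L,
                            window_length = 50L, window_step = 1L,
                            histogram_bins = 20L, q_level = 0.05,
                            associations = TRUE, out_dir = NULL) {
  arm <- match.arg(arm)
  structure(list(cohort = cohort, input_dir = input_dir, arm = arm,
                 morph_measures = morph_measures, bin_min = bin_min,
                 bin_max = bin_max, bin_step = bin_step,
                 single_bins = single_bins, window_length = window_length,
                 window_step = window_step, histogram_bins = histogram_bins,
                 q_level = q_level, associations = associations,
                 out_dir = out_dir),
            class = "pipeline_config")
}

nodal_metrics <- c("Enodal", "Elocal", "DC", "BC", "EC", "PC")

topology_of_matrix <- function(m) compute_topology(omst_backbone(absolutize(m)))

# Long topology rows for one subject/measure over a list of tagged matrices;
# the per-graph `measure` column of compute_topology() becomes `metric` so it
# does not collide with the morphometric measure tag.
topology_rows <- function(subject, arm, measure, mats, scales) {
  do.call(rbind, lapply(seq_along(mats), function(k) {
    tt <- topology_of_matrix(mats[[k]])
    data.frame(subject = subject, arm = arm, measure = measure,
               scale = scales[k], node = tt$node, metric = tt$measure,
               value = tt$value, stringsAsFactors = FALSE)
  }))
}

scale_series_stats <- function(values, bins, with_distribution) {
  out <- c(cv = tryCatch(coefficient_of_variation(values),
                         error = function(e) NA_real_))
  if (with_distribution) {
    ds <- distribution_summary(values, bins)
    out <- c(out, median = ds$median, mode = ds$mode, fwhm = ds$fwhm,
             fitted_median = ds$fitted_median, fitted_mode = ds$fitted_mode,
             fitted_fwhm = ds$fitted_fwhm)
  }
  out
}

summarize_variation <- function(topo, axis, bins, with_distribution) {
  nod <- topo[topo$node != "global", , drop = FALSE]
  parts <- split(nod, list(nod$subject, nod$measure, nod$node, nod$metric),
                 drop = TRUE)
  do.call(rbind, lapply(parts, function(d) {
    st <- scale_series_stats(d$value[order(d$scale)], bins, with_distribution)
    data.frame(subject = d$subject[1L], arm = d$arm[1L],
               measure = d$measure[1L], axis = axis, node = d$node[1L],
               metric = d$metric[1L], statistic = names(st),
               value = as.numeric(st), stringsAsFactors = FALSE)
  }))
}

# subjects x parcels matrix of one (measure, metric, statistic) slice.
stat_matrix_from <- function(df, subjects, nodes, value_col = "value") {
  m <- matrix(NA_real_, length(subjects), length(nodes),
              dimnames = list(subjects, nodes))
  m[cbind(match(df$subject, subjects), match(df$node, nodes))] <-
    df[[value_col]]
  m
}

#' Run the full analysis pipeline
#'
#' Executes the structural arm (vertex-wise morphometry -> similarity
#' networks over the bin sweep -> OMST backbones -> topological measures ->
#' spatial CV -> partial-correlation families) and/or the functional arm
#' (parcel time series -> static and sliding-window networks -> OMST ->
#' topology -> temporal CV and window-distribution statistics ->
#' partial-correlation families), deterministically given the cohort seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `topology`, `variation`, `associations` (long-format
#'   data.frames) and `manifest`; also written as TSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$input_dir)) {
    raw <- read_cohort(config$input_dir)
    cohort <- list(behavior = raw$behavior, morphometry = raw$morphometry,
                   bold = raw$bold)
    seed <- raw$manifest$seed
  } else {
    cohort <- simulate_cohort(config$cohort)
    seed <- config$cohort$seed
  }
  behavior <- cohort$behavior
  subjects <- behavior$subject
  topo_all <- list()
  vari_all <- list()
  assoc_all <- list()

  do_struct <- config$arm %in% c("both", "structural")
  do_func <- config$arm %in% c("both", "functional")

  if (do_struct) {
    bins <- seq.int(config$bin_min, config$bin_max, by = config$bin_step)
    for (s in subjects) {
      for (m in config$morph_measures) {
        tab <- cohort$morphometry[[s]][[m]]
        if (is.null(tab)) stop("structural stage: no ", m, " table for ", s)
        mats <- lapply(bins, function(b) build_morph_network(tab, b))
        topo_all[[paste("st", s, m)]] <-
          topology_rows(s, "structural", m, mats, bins)
        if (!config$single_bins %in% bins) {
          m1 <- build_morph_network(tab, config$single_bins)
          topo_all[[paste("st1", s, m)]] <-
            topology_rows(s, "structural", m, list(m1), config$single_bins)
        }
      }
    }
  }

  if (do_func) {
    for (s in subjects) {
      ts <- cohort$bold[[s]]
      if (is.null(ts)) stop("functional stage: no time series for ", s)
      topo_all[[paste("fs", s)]] <-
        topology_rows(s, "functional", "fc_static", list(static_fc(ts)), NA)
      wins <- sliding_window_fc(ts, config$window_length, config$window_step)
      topo_all[[paste("fd", s)]] <-
        topology_rows(s, "functional", "fc_dynamic", wins,
                      as.integer(names(wins)))
    }
  }

  topology <- do.call(rbind, topo_all)
  rownames(topology) <- NULL

  if (do_struct) {
    st <- topology[topology$arm == "structural" & !is.na(topology$scale), ]
    vari_all$spatial <- summarize_variation(st, "spatial_bins",
                                            config$histogram_bins, FALSE)
  }
  if (do_func) {
    dy <- topology[topology$measure == "fc_dynamic", ]
    vari_all$temporal <- summarize_variation(dy, "temporal_windows",
                                             config$histogram_bins, TRUE)
  }
  variation <- do.call(rbind, vari_all)
  rownames(variation) <- NULL

  nodes <- setdiff(unique(topology$node), "global")
  n_cov <- max(lengths(covariate_sets)) + 1L
  if (config$associations && length(subjects) > n_cov + 2L) {
    outcomes <- c("state_anxiety", "trait_anxiety")
    add_family <- function(df, arm, measure, statistic, morph_measure) {
      for (oc in outcomes) {
        sm <- stat_matrix_from(df, subjects, nodes)
        if (anyNA(sm)) next
        if (any(apply(sm, 2, stats::sd) == 0)) next
        assoc_all[[length(assoc_all) + 1L]] <<-
          run_family(sm, behavior, oc, arm, morph_measure, config$q_level,
                     measure = measure, statistic = statistic)
      }
    }
    if (do_struct) {
      for (m in config$morph_measures) {
        single <- topology[topology$measure == m &
                             topology$scale == config$single_bins &
                             topology$node != "global", ]
        cvs <- variation[variation$measure == m &
                           variation$statistic == "cv", ]
        for (met in nodal_metrics) {
          add_family(single[single$metric == met, ], "structural", m,
                     paste0(met, "_single"), m)
          add_family(cvs[cvs$metric == met, ], "structural", m,
                     paste0(met, "_cv"), m)
        }
      }
    }
    if (do_func) {
      stat_names <- c("cv", "median", "mode", "fwhm", "fitted_median",
                      "fitted_mode", "fitted_fwhm")
      single <- topology[topology$measure == "fc_static" &
                           topology$node != "global", ]
      temp <- variation[variation$axis == "temporal_windows", ]
      for (met in nodal_metrics) {
        add_family(single[single$metric == met, ], "functional", "fc_static",
                   paste0(met, "_single"), NULL)
        for (st in stat_names) {
          add_family(temp[temp$metric == met & temp$statistic == st, ],
                     "functional", "fc_dynamic", paste0(met, "_", st), NULL)
        }
      }
    }
  }
  associations <- if (length(assoc_all)) do.call(rbind, assoc_all) else NULL

  manifest <- list(seed = seed, arm = config$arm,
                   n_subjects = length(subjects),
                   bin_sweep = if (do_struct)
                     seq.int(config$bin_min, config$bin_max,
                             by = config$bin_step) else NULL,
                   window_length = config$window_length,
                   window_step = config$window_step,
                   histogram_bins = config$histogram_bins,
                   q_level = config$q_level,
                   rows = list(topology = nrow(topology),
                               variation = nrow(variation),
                               associations =
                                 if (is.null(associations)) 0L
                                 else nrow(associations)),
                   package_version =
                     as.character(utils::packageVersion("braintopo")),
                   started = format(t0), finished = format(Sys.time()))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(topology, file.path(config$out_dir, "topology.tsv"))
    write_tsv(variation, file.path(config$out_dir, "variation.tsv"))
    if (!is.null(associations))
      write_tsv(associations, file.path(config$out_dir, "associations.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(topology = topology, variation = variation,
       associations = associations, manifest = manifest)
}
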