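#' Default behavior moments for the synthetic cohort
#'
#' Means, standard deviations and correlations of the anxiety scores and
#' demographic covariates used by [generate_behavior()]: state anxiety
#' 34.20 (SD 9.33), trait anxiety 34.63 (SD 9.24), age 37.81 (SD 13.10)
#' years, education 15.48 (SD 3.10) years, state-trait correlation 0.848,
#' age-education correlation -0.464, and the small anxiety-demographic
#' correlations of the study cohort.
#'
#' @return List with `means`, `sds` (named vectors over `state_anxiety`,
#'   `trait_anxiety`, `age`, `education`) and `cors` (4 x 4 correlation
#'   matrix).
#' @export
default_behavior_moments <- function() {
  vars <- c("state_anxiety", "trait_anxiety", "age", "education")
  cors <- diag(4)
  dimnames(cors) <- list(vars, vars)
  cors["state_anxiety", "trait_anxiety"] <- 0.848
  cors["state_anxiety", "age"] <- -0.160
  cors["trait_anxiety", "age"] <- -0.177
  cors["state_anxiety", "education"] <- 0.087
  cors["trait_anxiety", "education"] <- 0.106
  cors["age", "education"] <- -0.464
  cors[lower.tri(cors)] <- t(cors)[lower.tri(cors)]
  list(means = stats::setNames(c(34.20, 34.63, 37.81, 15.48), vars),
       sds = stats::setNames(c(9.33, 9.24, 13.10, 3.10), vars),
       cors = cors)
}

#' Configuration of a synthetic cohort
#'
#' Collects every knob of the synthetic-data generator. Defaults reproduce
#' the study conditions: 60 subjects, 30 parcels with the retained-roster
#' vertex counts, 235 time points at TR = 2 s, BOLD power restricted to
#' 0.01-0.1 Hz, and behavior moments from [default_behavior_moments()].
#'
#' @param n_subjects Number of subjects.
#' @param n_timepoints BOLD time points per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param parcels Parcel roster data.frame (see [retained_parcels()]).
#' @param behavior_moments List as returned by [default_behavior_moments()].
#' @param morph_effects List of planted morphometry effects, each a list
#'   with `parcel`, `measure`, `beta`, `dimension` (`"state_anxiety"` or
#'   `"trait_anxiety"`); `beta` scales the parcel's log-scale spread per SD
#'   of the anxiety dimension.
#' @param bold_effects List of planted BOLD effects, each a list with
#'   `parcel`, `beta`, `dimension`; `beta` shifts the parcel's network
#'   coupling per SD of the anxiety dimension.
#' @param bold_coupling Baseline within-network coupling (variance share of
#'   the shared network signal) in \[0, 1\].
#' @param bold_states Number of piecewise-stationary coupling states across
#'   the scan (1 = stationary).
#' @param bold_state_couplings Coupling values cycled over the states.
#' @param band Passband of the BOLD signal in Hz.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L, n_timepoints = 235L,
                          tr_seconds = 2.0, parcels = retained_parcels(),
                          behavior_moments = default_behavior_moments(),
                          morph_effects = list(), bold_effects = list(),
                          bold_coupling = 0.3, bold_states = 1L,
                          bold_state_couplings = c(0.8, 0.0),
                          band = c(0.01, 0.1), seed = 20220623L) {
  stopifnot(n_subjects >= 1, n_timepoints >= 2, tr_seconds > 0,
            nrow(parcels) >= 2, all(parcels$vertex_count >= 1),
            all(behavior_moments$sds > 0),
            all(abs(behavior_moments$cors) <= 1),
            bold_coupling >= 0, bold_coupling <= 1, bold_states >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, parcels = parcels,
                 behavior_moments = behavior_moments,
                 morph_effects = morph_effects, bold_effects = bold_effects,
                 bold_coupling = bold_coupling,
                 bold_states = as.integer(bold_states),
                 bold_state_couplings = bold_state_couplings,
                 band = band, seed = as.integer(seed)),
            class = "cohort_config")
}

subject_ids <- function(n) sprintf("sub-%03d", seq_len(n))

#' Generate the behavior and covariate table
#'
#' Samples anxiety scores, age and education from a multivariate normal
#' with the configured moments; gender is Bernoulli(0.5); intracranial
#' volume, morphometric totals, mean framewise displacement and the BBR
#' registration cost are drawn from plausible marginal distributions
#' (mcBBR below the 0.65 exclusion bound, since the synthetic cohort
#' emulates retained subjects).
#'
#' @param config A [cohort_config()].
#' @return data.frame with one row per subject: `subject`, `state_anxiety`,
#'   `trait_anxiety`, `age`, `gender`, `education`, `ICV`, `total_volume`,
#'   `total_area`, `mean_thickness`, `meanFD`, `mcBBR`.
#' @export
generate_behavior <- function(config) {
  bm <- config$behavior_moments
  sigma <- diag(bm$sds) %*% bm$cors %*% diag(bm$sds)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  # singular-but-PSD structures (e.g. a requested correlation of exactly 1)
  # are legal degenerate cases; genuinely indefinite ones are not
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("requested correlation structure is not positive semi-definite")
  n <- config$n_subjects
  with_local_seed(config$seed, {
    scores <- MASS::mvrnorm(n, mu = bm$means, Sigma = sigma)
    scores <- matrix(scores, nrow = n,
                     dimnames = list(NULL, names(bm$means)))
    data.frame(subject = subject_ids(n),
               state_anxiety = scores[, "state_anxiety"],
               trait_anxiety = scores[, "trait_anxiety"],
               age = scores[, "age"],
               gender = stats::rbinom(n, 1L, 0.5),
               education = scores[, "education"],
               ICV = stats::rnorm(n, 1.45e6, 1.4e5),
               total_volume = stats::rnorm(n, 5.5e5, 5e4),
               total_area = stats::rnorm(n, 1.7e5, 1.5e4),
               mean_thickness = stats::rnorm(n, 2.6, 0.12),
               meanFD = stats::rlnorm(n, log(0.08), 0.4),
               mcBBR = stats::runif(n, 0.35, 0.62),
               stringsAsFactors = FALSE)
  })
}

anxiety_zscores <- function(behavior, dimension) {
  x <- behavior[[dimension]]
  as.vector(scale(x))
}

morph_base_params <- list(
  volume = list(meanlog = log(20), sdlog = 0.35),
  area = list(meanlog = log(0.6), sdlog = 0.30),
  thickness = list(meanlog = log(2.5), sdlog = 0.15))

#' Generate vertex-wise morphometry tables
#'
#' For each subject, parcel and measure (cortical volume, surface area,
#' thickness), draws `vertex_count` values from a parcel-specific lognormal
#' distribution (morphometry is positive and right-skewed), multiplied by a
#' subject-level scale factor. A planted effect widens or narrows the
#' parcel's log-scale spread linearly in the subject's standardized anxiety
#' score, which changes the histogram shape the similarity network sees.
#'
#' @param config A [cohort_config()].
#' @param behavior Output of [generate_behavior()] for the same config.
#' @param measures Morphometric measures to generate.
#' @return Named list (subject) of named lists (measure) of
#'   `VertexValueTable`s: named lists mapping parcel name to its vector of
#'   vertex values.
#' @export
generate_morphometry <- function(config, behavior,
                                 measures = c("volume", "area", "thickness")) {
  parcels <- config$parcels
  if (any(parcels$vertex_count < 1)) stop("zero vertex_count parcel")
  n <- config$n_subjects
  stopifnot(nrow(behavior) == n)
  effects <- config$morph_effects
  z_eff <- lapply(effects, function(e)
    e$beta * anxiety_zscores(behavior, e$dimension))
  with_local_seed(config$seed + 1L, {
    # parcel-level location offsets, fixed across subjects
    offsets <- lapply(measures, function(m)
      stats::setNames(stats::rnorm(nrow(parcels), 0, 0.10), parcels$name))
    names(offsets) <- measures
    subj_scale <- stats::rnorm(n, 1, 0.05)
    out <- lapply(seq_len(n), function(s) {
      per_measure <- lapply(measures, function(m) {
        base <- morph_base_params[[m]]
        tab <- lapply(seq_len(nrow(parcels)), function(p) {
          pname <- parcels$name[p]
          sdlog <- base$sdlog
          for (k in seq_along(effects)) {
            e <- effects[[k]]
            if (identical(e$parcel, pname) && identical(e$measure, m))
              sdlog <- sdlog * exp(z_eff[[k]][s])
          }
          subj_scale[s] * stats::rlnorm(parcels$vertex_count[p],
                                        base$meanlog + offsets[[m]][pname],
                                        sdlog)
        })
        stats::setNames(tab, parcels$name)
      })
      stats::setNames(per_measure, measures)
    })
    stats::setNames(out, subject_ids(n))
  })
}

# Band-limited Gaussian noise: white noise masked in the frequency domain so
# all spectral power lies in [band] Hz, then inverse-transformed and scaled
# to unit SD. Columns are independent series.
band_limited_noise <- function(n_t, tr, band, n_series) {
  freq <- seq(0, n_t - 1) / (n_t * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to physical frequency
  keep <- freq >= band[1] & freq <= band[2]
  x <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n_t
  out <- scale(out, center = TRUE, scale = apply(out, 2, stats::sd))
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  out
}

#' Generate parcel-average BOLD time series
#'
#' Per subject, a parcels x time-points matrix of band-limited Gaussian
#' signals (all spectral power inside the configured 0.01-0.1 Hz band at
#' TR = 2 s) with block correlation by Yeo network: each parcel mixes a
#' shared network signal with private noise according to the coupling
#' `c` (`x = sqrt(c) * shared + sqrt(1 - c) * private`). With more than one
#' coupling state the scan is split into equal piecewise-stationary
#' segments cycling through `bold_state_couplings`, exercising the dynamic
#' FC analysis. A planted effect shifts one parcel's coupling linearly in
#' the subject's standardized anxiety score.
#'
#' @inheritParams generate_morphometry
#' @return Named list of parcels x `n_timepoints` matrices, one per subject,
#'   with parcel names as rownames.
#' @export
generate_bold <- function(config, behavior) {
  tr <- config$tr_seconds
  band <- config$band
  if (band[2] > 1 / (2 * tr))
    stop(sprintf("band upper edge %.3f Hz exceeds the Nyquist frequency %.3f Hz",
                 band[2], 1 / (2 * tr)))
  stopifnot(band[1] < band[2], band[1] >= 0)
  parcels <- config$parcels
  np <- nrow(parcels)
  n_t <- config$n_timepoints
  n <- config$n_subjects
  stopifnot(nrow(behavior) == n)
  nets <- unique(parcels$network)
  net_of <- match(parcels$network, nets)
  # per-timepoint coupling multiplier from the piecewise-stationary states
  state_of_t <- if (config$bold_states > 1L) {
    rep(seq_len(config$bold_states), each = ceiling(n_t / config$bold_states),
        length.out = n_t)
  } else rep(1L, n_t)
  state_coupling <- if (config$bold_states > 1L) {
    rep_len(config$bold_state_couplings, config$bold_states)
  } else config$bold_coupling

  effects <- config$bold_effects
  z_eff <- lapply(effects, function(e)
    e$beta * anxiety_zscores(behavior, e$dimension))

  with_local_seed(config$seed + 2L, {
    out <- lapply(seq_len(n), function(s) {
      shared <- band_limited_noise(n_t, tr, band, length(nets))
      private <- band_limited_noise(n_t, tr, band, np)
      shift_p <- rep(0, np)
      for (k in seq_along(effects)) {
        e <- effects[[k]]
        p <- match(e$parcel, parcels$name)
        if (is.na(p)) stop("unknown parcel in bold effect: ", e$parcel)
        shift_p[p] <- shift_p[p] + z_eff[[k]][s]
      }
      c_t <- outer(shift_p, state_coupling[state_of_t], `+`)  # parcels x T
      c_t <- pmin(1, pmax(0, c_t))
      x <- sqrt(c_t) * t(shared[, net_of, drop = FALSE]) +
        sqrt(1 - c_t) * t(private)
      rownames(x) <- parcels$name
      x
    })
    stats::setNames(out, subject_ids(n))
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_behavior()], [generate_morphometry()] and
#' [generate_bold()] under the configured seed and bundles the results.
#'
#' @inheritParams generate_behavior
#' @return List of class `bt_cohort` with `config`, `behavior`,
#'   `morphometry`, `bold`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  behavior <- generate_behavior(config)
  structure(list(config = config,
                 behavior = behavior,
                 morphometry = generate_morphometry(config, behavior),
                 bold = generate_bold(config, behavior)),
            class = "bt_cohort")
}
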