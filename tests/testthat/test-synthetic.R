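test_that("behavior moments are reproduced at large n", {
  cfg <- cohort_config(n_subjects = 10000, seed = 101)
  beh <- generate_behavior(cfg)
  bm <- default_behavior_moments()
  n <- nrow(beh)
  for (v in names(bm$means)) {
    se <- bm$sds[[v]] / sqrt(n)
    expect_lt(abs(mean(beh[[v]]) - bm$means[[v]]), 3 * se)
    expect_lt(abs(sd(beh[[v]]) / bm$sds[[v]] - 1), 3 / sqrt(2 * n))
  }
  expect_lt(abs(cor(beh$state_anxiety, beh$trait_anxiety) - 0.848), 0.02)
  expect_lt(abs(cor(beh$age, beh$education) - (-0.464)), 0.03)
  expect_lt(abs(mean(beh$gender) - 0.5), 3 * 0.5 / sqrt(n))
  expect_true(all(beh$mcBBR <= 0.65))
  expect_false(anyNA(beh))
})

test_that("requested independence and degenerate correlation are honored", {
  bm <- default_behavior_moments()
  bm$cors[] <- diag(4)
  cfg <- cohort_config(n_subjects = 10000, behavior_moments = bm, seed = 102)
  beh <- generate_behavior(cfg)
  cm <- cor(beh[, names(bm$means)])
  expect_lt(max(abs(cm[upper.tri(cm)])), 3.5 / sqrt(10000))
  # requested r = 1: columns equal up to an affine map (the two scores must
  # then correlate identically with everything else, so start from identity)
  bm2 <- default_behavior_moments()
  bm2$cors[] <- diag(4)
  bm2$cors["state_anxiety", "trait_anxiety"] <- 1
  bm2$cors["trait_anxiety", "state_anxiety"] <- 1
  cfg2 <- cohort_config(n_subjects = 200, behavior_moments = bm2, seed = 103)
  beh2 <- generate_behavior(cfg2)
  expect_equal(cor(beh2$state_anxiety, beh2$trait_anxiety), 1)
  # an indefinite request errors
  bm3 <- default_behavior_moments()
  bm3$cors["state_anxiety", "trait_anxiety"] <- 0.99
  bm3$cors["trait_anxiety", "state_anxiety"] <- 0.99
  bm3$cors["state_anxiety", "age"] <- 0.9
  bm3$cors["age", "state_anxiety"] <- 0.9
  bm3$cors["trait_anxiety", "age"] <- -0.9
  bm3$cors["age", "trait_anxiety"] <- -0.9
  cfg3 <- cohort_config(n_subjects = 10, behavior_moments = bm3, seed = 104)
  expect_error(generate_behavior(cfg3), "positive semi-definite")
})

small_cfg <- function(...) {
  cohort_config(n_subjects = 3, parcels = retained_parcels()[c(1:5, 20), ],
                seed = 105, ...)
}

test_that("same seed gives bit-identical cohorts", {
  c1 <- simulate_cohort(small_cfg())
  c2 <- simulate_cohort(small_cfg())
  expect_identical(c1$behavior, c2$behavior)
  expect_identical(c1$morphometry, c2$morphometry)
  expect_identical(c1$bold, c2$bold)
  c3 <- simulate_cohort(cohort_config(n_subjects = 3,
                                      parcels = retained_parcels()[c(1:5, 20), ],
                                      seed = 106))
  expect_false(identical(c1$bold, c3$bold))
})

test_that("morphometry tables have the right shape and positivity", {
  cfg <- small_cfg()
  beh <- generate_behavior(cfg)
  mo <- generate_morphometry(cfg, beh)
  expect_length(mo, 3L)
  expect_named(mo[[1]], c("volume", "area", "thickness"))
  vc <- cfg$parcels$vertex_count
  for (m in names(mo[[1]]))
    expect_equal(unname(lengths(mo[[1]][[m]])), vc)
  expect_true(all(unlist(mo[[1]]$volume) > 0))
  # zero vertex count is rejected at configuration time
  bad <- retained_parcels()[1:3, ]
  bad$vertex_count[2] <- 0L
  expect_error(cohort_config(parcels = bad))
})

test_that("null planted effect leaves parcel spread unrelated to anxiety", {
  cfg <- cohort_config(n_subjects = 50, parcels = retained_parcels()[1:6, ],
                       seed = 107)
  beh <- generate_behavior(cfg)
  mo <- generate_morphometry(cfg, beh, measures = "volume")
  sdlog <- vapply(names(mo), function(s)
    sd(log(mo[[s]]$volume[[1]])), numeric(1))
  ct <- cor.test(sdlog, beh$state_anxiety)
  expect_gt(ct$p.value, 0.01)
  # planted spread effect is visible in the generated values
  cfge <- cohort_config(n_subjects = 50, parcels = retained_parcels()[1:6, ],
                        seed = 107,
                        morph_effects = list(list(parcel = "LH_Vis",
                                                  measure = "volume",
                                                  beta = 0.8,
                                                  dimension = "state_anxiety")))
  moe <- generate_morphometry(cfge, beh, measures = "volume")
  sdloge <- vapply(names(moe), function(s)
    sd(log(moe[[s]]$volume[["LH_Vis"]])), numeric(1))
  expect_gt(cor(sdloge, beh$state_anxiety), 0.5)
})

test_that("BOLD is band-limited with network block structure", {
  cfg <- cohort_config(n_subjects = 1, parcels = retained_parcels()[1:10, ],
                       n_timepoints = 800, seed = 108, bold_coupling = 0.6)
  beh <- generate_behavior(cfg)
  ts <- generate_bold(cfg, beh)[[1]]
  expect_equal(dim(ts), c(10L, 800L))
  # at least 80% of spectral power inside 0.01-0.1 Hz at TR 2 s
  f <- seq(0, by = 1 / (800 * 2), length.out = 800)
  f <- pmin(f, 1 / 2 - f)
  for (p in 1:3) {
    sp <- Mod(fft(ts[p, ]))^2
    expect_gte(sum(sp[f >= 0.01 & f <= 0.1]) / sum(sp), 0.8)
  }
  # same-network parcels correlate more than different-network ones
  fc <- static_fc(ts)
  nets <- cfg$parcels$network
  same <- outer(nets, nets, "==") & upper.tri(fc)
  diff_net <- outer(nets, nets, "!=") & upper.tri(fc)
  if (any(same)) expect_gt(mean(fc[same]), mean(fc[diff_net]) + 0.2)
})

test_that("perfect and zero coupling bound the FC", {
  parcels <- retained_parcels()[1:4, ]  # two Vis/SomMot pairs? use one net
  parcels <- retained_parcels()[retained_parcels()$network == "Vis", ]
  cfg1 <- cohort_config(n_subjects = 1, parcels = parcels,
                        n_timepoints = 300, bold_coupling = 1, seed = 109)
  beh1 <- generate_behavior(cfg1)
  ts1 <- generate_bold(cfg1, beh1)[[1]]
  expect_equal(static_fc(ts1)[1, 2], 1)
  cfg0 <- cohort_config(n_subjects = 1, parcels = retained_parcels()[1:6, ],
                        n_timepoints = 2000, bold_coupling = 0, seed = 110)
  beh0 <- generate_behavior(cfg0)
  fc0 <- static_fc(generate_bold(cfg0, beh0)[[1]])
  expect_lt(max(abs(fc0[upper.tri(fc0)])), 0.15)
})

test_that("band incompatible with the TR is rejected", {
  cfg <- cohort_config(n_subjects = 1, parcels = retained_parcels()[1:4, ],
                       band = c(0.1, 0.3), seed = 111)
  beh <- generate_behavior(cfg)
  expect_error(generate_bold(cfg, beh), "Nyquist")
})

test_that("piecewise-stationary coupling shows up in sliding-window FC", {
  parcels <- retained_parcels()[retained_parcels()$network == "Vis", ]
  cfg <- cohort_config(n_subjects = 1, parcels = parcels, n_timepoints = 480,
                       bold_states = 4L, bold_state_couplings = c(0.9, 0.0),
                       seed = 112)
  beh <- generate_behavior(cfg)
  ts <- generate_bold(cfg, beh)[[1]]
  wins <- sliding_window_fc(ts, window = 40, step = 4)
  fcs <- vapply(wins, function(m) m[1, 2], numeric(1))
  starts <- as.integer(names(wins))
  seg <- ((starts + 20) - 1) %/% 120 + 1      # state of the window center
  inside <- (starts - 1) %/% 120 == (starts + 38) %/% 120  # fully inside
  hi <- fcs[inside & seg %in% c(1, 3)]
  lo <- fcs[inside & seg %in% c(2, 4)]
  expect_gt(mean(hi), mean(lo) + 0.4)
})
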