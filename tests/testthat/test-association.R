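test_that("partial correlation reduces to Pearson with no covariates", {
  set.seed(91)
  y <- rnorm(40)
  x <- rnorm(40)
  res <- partial_correlation(y, x)
  expect_equal(res$r, cor(y, x))
  expect_equal(res$df, 38L)
  expect_equal(res$p, cor.test(y, x)$p.value)
})

test_that("residual route equals the GLM-coefficient route", {
  set.seed(92)
  for (k in 1:10) {
    n <- 60
    z <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
    y <- rnorm(n) + z %*% runif(4)
    x <- rnorm(n) + z %*% runif(4)
    res <- partial_correlation(as.vector(y), as.vector(x), z)
    fit <- summary(lm(y ~ z + x))
    tx <- fit$coefficients["x", "t value"]
    expect_equal(res$t, tx, tolerance = 1e-10)
    expect_equal(res$p, fit$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(res$df, n - 4L - 2L)
    # r and p are invariant to covariate rescaling
    res2 <- partial_correlation(as.vector(y), as.vector(x),
                                sweep(z, 2, c(10, 0.1, 1000, 1), `*`))
    expect_equal(res2$r, res$r)
  }
})

test_that("degenerate and invalid inputs are flagged", {
  set.seed(93)
  z <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  # predictor an exact linear combination of the covariates
  expect_warning(res <- partial_correlation(y, z %*% c(1, -2), z),
                 "no residual variance")
  expect_true(is.na(res$r))
  # collinear covariates are named
  zz <- cbind(z, dup = z[, "a"])
  expect_error(partial_correlation(y, rnorm(30), zz), "dup")
  expect_error(partial_correlation(y[1:5], rnorm(5),
                                   matrix(rnorm(20), 5, 4)), "n >")
  expect_error(partial_correlation(c(y[-1], NA), rnorm(30), z), "missing")
})

test_that("BH correction matches the step-up definition", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    passed <- which(p[o] <= q * seq_len(m) / m)
    flags <- logical(m)
    if (length(passed)) flags[o[seq_len(max(passed))]] <- TRUE
    flags
  }
  set.seed(94)
  cases <- list(rep(0.001, 30), rep(1, 30),
                c(0.001, 0.01, 0.02, 0.03, seq(0.04, 0.9, length.out = 26)),
                runif(30))
  for (p in cases) {
    got <- fdr_correct(p, 0.05)
    expect_equal(got$significant, bh_oracle(p, 0.05))
    expect_true(all(got$q >= p - 1e-15))
    # order invariance
    perm <- sample(length(p))
    expect_equal(fdr_correct(p[perm], 0.05)$q, got$q[perm])
  }
  expect_true(all(fdr_correct(rep(0.001, 30))$significant))
  expect_false(any(fdr_correct(rep(1, 30))$significant))
})

# synthetic family: behavior plus a subjects x 30 statistic matrix in which
# parcel `planted` has true partial correlation rho with the outcome
make_family <- function(n, rho = 0, planted = NULL,
                        outcome = "state_anxiety") {
  cfg <- cohort_config(n_subjects = n, seed = sample.int(2^30, 1))
  beh <- generate_behavior(cfg)
  covs <- as.matrix(beh[, c("age", "gender", "education", "mcBBR", "meanFD")])
  sm <- matrix(rnorm(n * 30), n,
               dimnames = list(NULL, retained_parcels()$name))
  if (!is.null(planted)) {
    ey <- resid(lm(beh[[outcome]] ~ covs))
    sm[, planted] <- rho * as.vector(scale(ey)) +
      sqrt(1 - rho^2) * rnorm(n)
  }
  list(behavior = beh, stats = sm)
}

test_that("run_family wires covariates, FDR and ordering together", {
  set.seed(95)
  fam <- make_family(60, rho = 0.9, planted = "RH_SalVentAttn_FrOper")
  res <- run_family(fam$stats, fam$behavior, "state_anxiety", "functional",
                    statistic = "PC_single")
  expect_equal(nrow(res), 30L)
  expect_equal(res$node[1], "RH_SalVentAttn_FrOper")  # sorted by p
  expect_true(res$significant[1])
  expect_gt(res$r[1], 0)
  expect_equal(res$df[1], 60L - 5L - 2L)
  expect_true(all(res$q >= res$p))
  # permuting subject rows consistently leaves results unchanged
  perm <- sample(60)
  res2 <- run_family(fam$stats[perm, ], fam$behavior[perm, ],
                     "state_anxiety", "functional", statistic = "PC_single")
  expect_equal(res2$r, res$r)
  expect_equal(res2$q, res$q)
  # structural arm requires a morph measure and its total covariate
  expect_error(run_family(fam$stats, fam$behavior, "state_anxiety",
                          "structural"), "morph_measure")
  res3 <- run_family(fam$stats, fam$behavior, "trait_anxiety", "structural",
                     morph_measure = "area")
  expect_equal(res3$df[1], 60L - 5L - 2L)
  # missing covariate column is reported
  beh2 <- fam$behavior; beh2$meanFD <- NULL
  expect_error(run_family(fam$stats, beh2, "state_anxiety", "functional"),
               "meanFD")
})

test_that("type-I error is nominal and planted sign is recovered", {
  set.seed(96)
  n_rep <- 300
  alpha <- 0.05
  hits <- 0L
  total <- 0L
  sign_ok <- 0L
  flag_ok <- 0L
  for (k in seq_len(n_rep)) {
    fam <- make_family(60)
    res <- run_family(fam$stats, fam$behavior, "state_anxiety", "functional")
    hits <- hits + sum(res$p < alpha)
    total <- total + nrow(res)
    famp <- make_family(60, rho = 0.5, planted = "LH_Vis")
    resp <- run_family(famp$stats, famp$behavior, "state_anxiety",
                       "functional")
    row <- resp[resp$node == "LH_Vis", ]
    sign_ok <- sign_ok + (row$r > 0)
    flag_ok <- flag_ok + (row$significant && row$r > 0)
  }
  rate <- hits / total
  # binomial error around the nominal level
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / total))
  expect_gte(sign_ok / n_rep, 0.95)
  # power to be BH-flagged at r = 0.5, n = 60 is high but below 1
  expect_gt(flag_ok / n_rep, 0.5)
})
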