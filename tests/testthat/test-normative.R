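make_cov <- function(n, seed = 1, sex_p = 0.5) {
  set.seed(seed)
  data.frame(age = stats::runif(n, 18, 65),
             sex = ifelse(stats::rbinom(n, 1, sex_p) == 1, "F", "M"))
}

test_that("constant targets give flat predictions with near-zero deviations", {
  cov <- make_cov(60, seed = 1)
  set.seed(2)
  y <- 0.4 + stats::rnorm(60, 0, 1e-4)
  m <- fit_gpr_region(cov, y, n_restarts = 2, seed = 3)
  pr <- predict_normative(m, cov)
  expect_equal(pr$mean, rep(0.4, 60), tolerance = 1e-3)
  z <- z_deviation(y, pr$mean, pr$var_f, pr$sigma2_n)
  expect_true(all(abs(z) < 4))
  expect_lt(mean(abs(z)), 1.2)
})

test_that("a planted linear age trend is recovered over the observed range", {
  cov <- make_cov(300, seed = 4)
  set.seed(5)
  y <- 0.5 - 0.003 * cov$age + stats::rnorm(300, 0, 0.01)
  m <- fit_gpr_region(cov, y, n_restarts = 2, seed = 6)
  grid <- data.frame(age = seq(20, 63, by = 1), sex = "M")
  pr <- predict_normative(m, grid)
  expect_true(all(abs(pr$mean - (0.5 - 0.003 * grid$age)) < 0.01))
  # noise variance estimate near the planted 1e-4
  expect_lt(abs(log(m$sigma2_n / 1e-4)), log(2.5))
})

test_that("GP posterior matches a direct linear-algebra evaluation on 5 points", {
  # independent oracle: build the kernel matrices by hand and use solve()
  theta <- c(sf2 = 0.5, ell = 0.8, wl = 0.2, sn2 = 0.1)
  cov_tr <- data.frame(age = c(20, 30, 40, 50, 60), sex = c(0, 1, 0, 1, 0))
  y <- c(0.3, 0.5, 0.45, 0.6, 0.2)
  m <- fit_gpr_region(cov_tr, y, hyperparams = theta)
  cov_te <- data.frame(age = c(25, 55), sex = c(1, 0))

  mu_a <- mean(cov_tr$age); sd_a <- stats::sd(cov_tr$age)
  enc <- function(d) cbind((d$age - mu_a) / sd_a, as.numeric(d$sex))
  A <- enc(cov_tr); As <- enc(cov_te)
  kf <- function(x1, x2) {
    theta[["sf2"]] * exp(-0.5 * (x1[1] - x2[1])^2 / theta[["ell"]]^2) +
      theta[["wl"]] * sum(x1 * x2)
  }
  Kmat <- outer(1:5, 1:5, Vectorize(function(i, j) kf(A[i, ], A[j, ])))
  Ks <- outer(1:2, 1:5, Vectorize(function(i, j) kf(As[i, ], A[j, ])))
  Kn <- Kmat + diag(theta[["sn2"]], 5)
  yc <- y - mean(y)
  mu_oracle <- mean(y) + Ks %*% solve(Kn, yc)
  var_oracle <- vapply(1:2, function(i) {
    kf(As[i, ], As[i, ]) - Ks[i, ] %*% solve(Kn, Ks[i, ])
  }, numeric(1))

  pr <- predict_normative(m, cov_te)
  expect_equal(pr$mean, as.numeric(mu_oracle), tolerance = 1e-8)
  expect_equal(pr$var_f, var_oracle, tolerance = 1e-8)
})

test_that("predictive variance grows away from the training support and flags extrapolation", {
  cov <- make_cov(100, seed = 7)
  set.seed(8)
  y <- 0.5 + 0.002 * cov$age + stats::rnorm(100, 0, 0.02)
  m <- fit_gpr_region(cov, y, n_restarts = 2, seed = 9)
  far <- predict_normative(m, data.frame(age = 95, sex = "M"))
  mid <- predict_normative(m, data.frame(age = stats::median(cov$age), sex = "M"))
  expect_gt(far$var_f, mid$var_f)
  expect_true(far$extrapolated)
  expect_false(mid$extrapolated)
})

test_that("z_deviation implements (y - mu) / sqrt(var_f + var_n) with guards", {
  expect_equal(z_deviation(5, 5, 0.5, 0.5), 0)
  s <- sqrt(0.3 + 0.1)
  expect_equal(z_deviation(1 + 2.6 * s, 1, 0.3, 0.1), 2.6)
  # vectorized case agrees elementwise with the scalar formula
  y <- c(1, 2, 3); mu <- c(0.5, 2, 4); vf <- c(0.1, 0.2, 0.3)
  expect_equal(z_deviation(y, mu, vf, 0.05),
               vapply(1:3, function(i) z_deviation(y[i], mu[i], vf[i], 0.05),
                      numeric(1)))
  expect_error(z_deviation(1, 0, -0.1, 0.1), "non-negative")
  expect_error(z_deviation(1, 0, 0, 0), "positive")
  # a Z exactly at the threshold is not counted extreme (strict inequality)
  Z <- matrix(c(2.6, -2.6, 2.61, 0), 1)
  idx <- deviation_indices(Z)
  expect_equal(idx$extreme_total, 1)
})

test_that("GPR beats a straight line on a planted quadratic trajectory", {
  set.seed(10)
  cov <- make_cov(240, seed = 10)
  f <- 0.5 + 0.004 * (cov$age - 40) - 0.00025 * (cov$age - 40)^2
  y <- f + stats::rnorm(240, 0, 0.02)
  tr <- 1:160; te <- 161:240
  m <- fit_gpr_region(cov[tr, ], y[tr], n_restarts = 2, seed = 11)
  pr <- predict_normative(m, cov[te, ])
  lin <- stats::lm(y ~ age + sex, data = cbind(cov, y = y)[tr, ])
  mse_gp <- mean((y[te] - pr$mean)^2)
  mse_lin <- mean((y[te] - stats::predict(lin, cov[te, ]))^2)
  expect_lt(mse_gp, mse_lin)
})

test_that("cross-validation anchors: near-noiseless fits give SMSE ~ 0, planted R2 gives SMSE ~ 1 - v", {
  set.seed(12)
  cov <- make_cov(150, seed = 12)
  # deterministic signal + tiny noise: SMSE near 0
  y0 <- 0.4 + 0.005 * cov$age + 0.02 * (cov$sex == "F") +
    stats::rnorm(150, 0, 0.002)
  cv0 <- crossval_metrics(matrix(y0, ncol = 1), cov, k_folds = 5, seed = 13,
                          n_restarts = 1)
  expect_lt(cv0$smse[1], 0.05)
  expect_lt(cv0$msll[1], -1)
  # age+sex explain a planted fraction v of variance: SMSE ~ 1 - v
  v <- 0.5
  set.seed(14)
  n <- 400
  cov2 <- make_cov(n, seed = 14)
  signal <- scale(0.01 * cov2$age + 0.1 * (cov2$sex == "F"))
  y2 <- sqrt(v) * as.numeric(signal) + sqrt(1 - v) * stats::rnorm(n)
  cv2 <- crossval_metrics(matrix(y2, ncol = 1), cov2, k_folds = 5, seed = 15,
                          n_restarts = 1)
  expect_equal(cv2$smse[1], 1 - v, tolerance = 0.12)
  expect_error(crossval_metrics(matrix(y2, ncol = 1), cov2, k_folds = 1),
               "k_folds")
})

test_that("normative range collapses at z = 0 and widens monotonically", {
  cov <- make_cov(80, seed = 16)
  set.seed(17)
  y <- 0.5 - 0.002 * cov$age + stats::rnorm(80, 0, 0.02)
  m <- fit_gpr_region(cov, y, n_restarts = 1, seed = 18)
  grid <- seq(20, 60, by = 5)
  b0 <- normative_range(m, grid, sex = "M", z_level = 0)
  expect_equal(b0$lower, b0$mean)
  expect_equal(b0$upper, b0$mean)
  b1 <- normative_range(m, grid, sex = "M", z_level = 1)
  b2 <- normative_range(m, grid, sex = "M", z_level = 2.6)
  expect_true(all(b2$upper - b2$lower > b1$upper - b1$lower))
})

test_that("trajectory clustering recovers planted increasing/decreasing patterns", {
  set.seed(19)
  n <- 80
  cov <- make_cov(n, seed = 19)
  n_reg <- 20
  kinds <- rep(c("increasing", "decreasing"), each = 10)
  slopes <- ifelse(kinds == "increasing", 1, -1) * 0.004
  feats <- vapply(seq_len(n_reg), function(r) {
    0.5 + slopes[r] * (cov$age - 40) + stats::rnorm(n, 0, 0.005)
  }, numeric(n))
  colnames(feats) <- sprintf("r%02d", seq_len(n_reg))
  ms <- fit_normative_set(feats, cov, n_restarts = 1, seed = 20)
  labels <- cluster_trajectories(ms, sex = "M", age_grid = seq(20, 60, 4))
  expect_equal(as.character(labels), kinds)
  # order invariance: reversing the region order permutes labels consistently
  ms_rev <- ms; ms_rev$models <- rev(ms$models)
  labels_rev <- cluster_trajectories(ms_rev, sex = "M", age_grid = seq(20, 60, 4))
  expect_equal(as.character(labels_rev), rev(kinds))
  # degenerate input: identical trajectories in every region
  ms_deg <- ms; ms_deg$models <- rep(ms$models[1], n_reg)
  expect_error(cluster_trajectories(ms_deg, sex = "M"), "degenerate")
})

test_that("held-out HC Z-scores from the model set pipeline are plausible and deterministic", {
  rs <- test_regions()
  cc <- cohort_config(n_hc = 120, n_mdd = 30, n_sites = 3, seed = 21)
  hc <- generate_hc_cohort(cc, rs)
  cov <- data.frame(age = hc$cohort$age, sex = hc$cohort$sex)
  h <- combat_harmonize(hc$features, hc$cohort$site_id,
                        data.frame(age = cov$age, sex = as.numeric(cov$sex == "F")))
  sub <- h[, seq(1, 246, by = 50)]
  cv1 <- crossval_metrics(sub, cov, k_folds = 5, seed = 22, n_restarts = 1)
  cv2 <- crossval_metrics(sub, cov, k_folds = 5, seed = 22, n_restarts = 1)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$Z, cv2$Z, tolerance = 1e-12)
  expect_lt(abs(mean(cv1$Z)), 0.15)
  expect_lt(abs(stats::var(as.numeric(cv1$Z)) - 1), 0.3)
})

test_that("normative model set serialization round trips predictions", {
  set.seed(23)
  cov <- make_cov(50, seed = 23)
  feats <- vapply(1:3, function(r) {
    0.5 - 0.002 * r * cov$age + stats::rnorm(50, 0, 0.02)
  }, numeric(50))
  colnames(feats) <- c("a", "b", "c")
  ms <- fit_normative_set(feats, cov, n_restarts = 1, seed = 24)
  p <- tempfile(fileext = ".json")
  write_normative_set(ms, p)
  ms2 <- read_normative_set(p)
  newcov <- data.frame(age = c(25, 45, 60), sex = c("M", "F", "M"))
  for (r in 1:3) {
    a <- predict_normative(ms$models[[r]], newcov)
    b <- predict_normative(ms2$models[[r]], newcov)
    expect_equal(a$mean, b$mean, tolerance = 1e-10)
    expect_equal(a$var_f, b$var_f, tolerance = 1e-10)
  }
})

test_that("fit_gpr_region enforces its preconditions", {
  cov <- make_cov(10, seed = 25)
  expect_error(fit_gpr_region(cov, stats::rnorm(10)), "n >= 20")
  cov2 <- data.frame(age = rep(40, 30), sex = rep("M", 30))
  expect_error(fit_gpr_region(cov2, stats::rnorm(30)), "age variance")
})
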