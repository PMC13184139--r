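# Shared fixtures, all generated in code.

test_regions <- function(seed = 1) generate_region_specs(seed = seed)

# small multi-site HC fixture with planted site effects
small_site_fixture <- function(n_per_site = 60, n_regions = 25, seed = 42,
                               gamma_sd = 0.3, scale_range = c(0.7, 1.5)) {
  set.seed(seed)
  n <- 3 * n_per_site
  site <- rep(c("a", "b", "c"), each = n_per_site)
  si <- as.integer(factor(site))
  age <- stats::runif(n, 18, 65)
  sexF <- stats::rbinom(n, 1, 0.5)
  slope <- stats::runif(n_regions, -0.01, 0.01)
  truth <- outer(age, slope) + matrix(stats::rnorm(n * n_regions, 0, 0.5), n)
  gamma <- matrix(stats::rnorm(3 * n_regions, 0, gamma_sd), 3)
  delta <- matrix(stats::runif(3 * n_regions, scale_range[1], scale_range[2]), 3)
  y <- truth * delta[si, ] + gamma[si, ]
  list(y = y, site = site, age = age, sexF = sexF, slope = slope,
       gamma = gamma, delta = delta)
}

# independent brute-force Kendall's W oracle: ranks + formula, no shortcuts
kendalls_w_oracle <- function(x) {
  n <- nrow(x); K <- ncol(x)
  ranks <- matrix(NA_real_, n, K)
  for (j in seq_len(K)) ranks[, j] <- rank(x[, j], ties.method = "average")
  R <- numeric(n)
  for (i in seq_len(n)) R[i] <- sum(ranks[i, ])
  Rbar <- mean(R)
  num <- sum(R^2) - n * Rbar^2
  num / (K^2 * (n^3 - n) / 12)
}
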