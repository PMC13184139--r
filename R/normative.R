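# Per-region Gaussian-process normative models of ReHo as a function of age
# and sex. Kernel: squared-exponential over standardized age (smooth
# nonlinear lifespan trend) + linear kernel over (age, sex) (linear drift
# and additive sex offset) + white noise. Hyperparameters maximize the log
# marginal likelihood (multi-restart L-BFGS-B, analytic gradients).
# Individuals are scored as Z = (y - mu) / sqrt(var_f + var_noise).

# covariate encoding: age standardized by training mean/sd, sex -> 0/1
.encode_covariates <- function(covariates, age_mean = NULL, age_sd = NULL) {
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  stopifnot(all(c("age", "sex") %in% names(covariates)))
  age <- as.numeric(covariates$age)
  sex <- covariates$sex
  if (is.numeric(sex)) sexn <- as.numeric(sex != 0) else {
    sexn <- as.numeric(as.character(sex) == "F")
  }
  if (is.null(age_mean)) { age_mean <- mean(age); age_sd <- stats::sd(age) }
  list(A = cbind(age_std = (age - age_mean) / age_sd, sex = sexn),
       age_mean = age_mean, age_sd = age_sd, age_raw = age)
}

# noise-free kernel between encoded covariate matrices
.gp_kernel <- function(A1, A2, theta) {
  sf2 <- theta[["sf2"]]; ell <- theta[["ell"]]; wl <- theta[["wl"]]
  D2 <- outer(A1[, 1], A2[, 1], "-")^2
  sf2 * exp(-0.5 * D2 / ell^2) + wl * (A1 %*% t(A2))
}

# negative log marginal likelihood and gradient in log-parameter space
.gp_nlml <- function(ltheta, A, yc) {
  th <- exp(ltheta)
  n <- length(yc)
  D2 <- outer(A[, 1], A[, 1], "-")^2
  E <- th[1] * exp(-0.5 * D2 / th[2]^2)
  Lin <- A %*% t(A)
  K <- E + th[3] * Lin + diag(th[4] + 1e-10, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, 4)))
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  nlml <- 0.5 * sum(yc * alpha) + sum(log(diag(ch))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(ch)
  Amat <- tcrossprod(alpha) - Kinv
  g <- c(
    sf2 = -0.5 * sum(Amat * E),
    ell = -0.5 * sum(Amat * (E * D2 / th[2]^2)),
    wl  = -0.5 * sum(Amat * (th[3] * Lin)),
    sn2 = -0.5 * sum(diag(Amat)) * th[4]
  )
  list(value = nlml, gradient = g)
}

#' Fit a per-region GPR normative model
#'
#' @param covariates Data frame with `age` (years) and `sex` (`"M"`/`"F"` or
#'   0/1); n >= 20 with non-degenerate age.
#' @param y Regional ReHo values, one per subject.
#' @param n_restarts Number of optimizer restarts (first start is a
#'   deterministic data-driven initialization, later ones jittered).
#' @param seed Seed for the restart jitter.
#' @param hyperparams Optional named vector `c(sf2, ell, wl, sn2)` to skip
#'   optimization (used for oracle checks and warm starts).
#' @param region_id Identifier carried into error messages and summaries.
#' @return Object of class `gpr_region_model`: hyperparameters, noise
#'   variance `sigma2_n`, training data, Cholesky factor, and the log
#'   marginal likelihood.
#' @export
fit_gpr_region <- function(covariates, y, n_restarts = 2, seed = 1,
                           hyperparams = NULL, region_id = NA) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(hyperparams)) {
    if (n < 20) stop("fit_gpr_region needs n >= 20")
  }
  enc <- .encode_covariates(covariates)
  if (stats::sd(enc$age_raw) <= 0 || !is.finite(stats::sd(enc$age_raw))) {
    stop("age variance must be positive")
  }
  ymean <- mean(y)
  yc <- y - ymean
  vy <- max(stats::var(y), 1e-12)

  if (is.null(hyperparams)) {
    base <- c(sf2 = 0.5 * vy, ell = 1, wl = 0.1 * vy, sn2 = 0.5 * vy)
    set.seed(seed)
    starts <- list(log(base))
    if (n_restarts > 1) {
      for (i in seq_len(n_restarts - 1)) {
        starts[[i + 1]] <- log(base) + stats::rnorm(4, 0, 1)
      }
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, fn = function(p) .gp_nlml(p, enc$A, yc)$value,
                     gr = function(p) .gp_nlml(p, enc$A, yc)$gradient,
                     method = "L-BFGS-B", lower = rep(-15, 4),
                     upper = rep(8, 4), control = list(maxit = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) {
      stop(sprintf("GPR optimization failed on all restarts (region %s)",
                   as.character(region_id)))
    }
    theta <- exp(best$par)
    names(theta) <- c("sf2", "ell", "wl", "sn2")
    lml <- -best$value
  } else {
    theta <- hyperparams[c("sf2", "ell", "wl", "sn2")]
    lml <- -.gp_nlml(log(theta), enc$A, yc)$value
  }

  K <- .gp_kernel(enc$A, enc$A, theta) + diag(theta[["sn2"]] + 1e-10, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(list(
    theta = theta, sigma2_n = theta[["sn2"]],
    A_train = enc$A, y_mean = ymean, alpha = alpha, chol = ch,
    age_mean = enc$age_mean, age_sd = enc$age_sd,
    age_range = range(enc$age_raw),
    log_marginal_likelihood = lml,
    n_train = n, region_id = region_id
  ), class = "gpr_region_model")
}

#' Posterior mean and variance of a fitted normative model
#'
#' Standard GP posterior at new covariates. The returned variance is the
#' latent-function variance \eqn{\sigma^2_f}; the noise variance
#' \eqn{\sigma^2_n} is reported separately. Ages outside the training range
#' are flagged as extrapolation.
#'
#' @param model A `gpr_region_model`.
#' @param covariates Data frame with `age` and `sex`.
#' @return List: `mean`, `var_f`, `sigma2_n`, `extrapolated` (logical).
#' @export
predict_normative <- function(model, covariates) {
  stopifnot(inherits(model, "gpr_region_model"))
  enc <- .encode_covariates(covariates, model$age_mean, model$age_sd)
  Ks <- .gp_kernel(enc$A, model$A_train, model$theta)
  mu <- model$y_mean + as.numeric(Ks %*% model$alpha)
  v <- forwardsolve(t(model$chol), t(Ks))
  kss <- model$theta[["sf2"]] + model$theta[["wl"]] * rowSums(enc$A^2)
  var_f <- pmax(kss - colSums(v^2), 0)
  extrap <- enc$age_raw < model$age_range[1] | enc$age_raw > model$age_range[2]
  list(mean = mu, var_f = var_f, sigma2_n = model$sigma2_n,
       extrapolated = extrap)
}

#' Z-deviation from a normative prediction
#'
#' \eqn{Z = (y - \mu) / \sqrt{\sigma^2_f + \sigma^2_n}}.
#'
#' @param y_true Observed values.
#' @param mu Predicted means.
#' @param var_f Predictive (latent) variances, >= 0.
#' @param sigma2_n Noise variance, > 0.
#' @return Numeric vector of Z-scores.
#' @export
z_deviation <- function(y_true, mu, var_f, sigma2_n) {
  if (any(var_f < 0)) stop("var_f must be non-negative")
  total <- var_f + sigma2_n
  if (any(total <= 0)) stop("total predictive variance must be positive")
  (y_true - mu) / sqrt(total)
}

#' Fit the full 246-region normative model set
#'
#' One independent GPR model per region (column of `features`).
#'
#' @param features HC subjects x regions matrix.
#' @param covariates Data frame with `age`, `sex` for the same subjects.
#' @param n_restarts,seed Passed to [fit_gpr_region()].
#' @param population_id Label stored with the set.
#' @return Object of class `normative_model_set`.
#' @export
fit_normative_set <- function(features, covariates, n_restarts = 2, seed = 1,
                              population_id = "HC") {
  features <- as.matrix(features)
  models <- lapply(seq_len(ncol(features)), function(r) {
    fit_gpr_region(covariates, features[, r], n_restarts = n_restarts,
                   seed = seed + r, region_id = colnames(features)[r] %||% r)
  })
  structure(list(models = models, feature_names = colnames(features),
                 population_id = population_id, n_regions = ncol(features)),
            class = "normative_model_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deviation map of new subjects under a fitted model set
#'
#' @param model_set A `normative_model_set`.
#' @param features Subjects x regions matrix (same region order as the fit).
#' @param covariates Data frame with `age`, `sex`.
#' @param threshold Extreme-deviation threshold stored with the map.
#' @return Subjects x regions matrix of Z-scores with attribute `threshold`.
#' @export
deviation_map <- function(model_set, features, covariates, threshold = 2.6) {
  stopifnot(inherits(model_set, "normative_model_set"))
  features <- as.matrix(features)
  stopifnot(ncol(features) == model_set$n_regions)
  Z <- vapply(seq_len(ncol(features)), function(r) {
    pr <- predict_normative(model_set$models[[r]], covariates)
    z_deviation(features[, r], pr$mean, pr$var_f, pr$sigma2_n)
  }, numeric(nrow(features)))
  if (nrow(features) == 1) Z <- matrix(Z, nrow = 1)
  dimnames(Z) <- dimnames(features)
  attr(Z, "threshold") <- threshold
  Z
}

#' 10-fold cross-validated accuracy and held-out HC deviations
#'
#' Per region and fold, the model is fitted on the remaining folds and the
#' held-out subjects are predicted. SMSE is the test MSE divided by the test
#' variance (1 = no better than the mean); MSLL is the mean Gaussian
#' negative log predictive density minus that of the trivial model using the
#' training mean and variance (0 = trivial, negative = better). The held-out
#' Z-scores are assembled into an HC deviation map.
#'
#' @param features HC subjects x regions matrix.
#' @param covariates Data frame with `age`, `sex`.
#' @param k_folds Number of folds (>= 2).
#' @param seed Seed for fold assignment and restarts.
#' @param n_restarts Optimizer restarts per fit.
#' @return List of class `cv_metrics`: `smse`, `msll` (per region), `folds`
#'   (assignment), and `Z` (held-out deviation map).
#' @export
crossval_metrics <- function(features, covariates, k_folds = 10, seed = 1,
                             n_restarts = 2) {
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  if (k_folds < 2) stop("k_folds must be >= 2")
  set.seed(seed)
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  if (min(table(folds)) < 2) stop("a fold has < 2 subjects; reduce k_folds")
  Z <- matrix(NA_real_, n, p, dimnames = dimnames(features))
  smse <- msll <- matrix(NA_real_, k_folds, p)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    cov_tr <- covariates[tr, , drop = FALSE]
    cov_te <- covariates[te, , drop = FALSE]
    for (r in seq_len(p)) {
      m <- fit_gpr_region(cov_tr, features[tr, r], n_restarts = n_restarts,
                          seed = seed + 1000 * f + r,
                          region_id = colnames(features)[r] %||% r)
      pr <- predict_normative(m, cov_te)
      yte <- features[te, r]
      tot <- pr$var_f + pr$sigma2_n
      Z[te, r] <- (yte - pr$mean) / sqrt(tot)
      smse[f, r] <- mean((yte - pr$mean)^2) / stats::var(yte)
      ytr <- features[tr, r]
      loss_model <- mean(0.5 * log(2 * pi * tot) + (yte - pr$mean)^2 / (2 * tot))
      v0 <- stats::var(ytr); m0 <- mean(ytr)
      loss_triv <- mean(0.5 * log(2 * pi * v0) + (yte - m0)^2 / (2 * v0))
      msll[f, r] <- loss_model - loss_triv
    }
  }
  structure(list(smse = colMeans(smse), msll = colMeans(msll),
                 folds = folds, Z = Z),
            class = "cv_metrics")
}

#' Normative range band
#'
#' \eqn{\mu \pm z \sqrt{\sigma^2_f + \sigma^2_n}} over an age grid for one sex.
#'
#' @param model A `gpr_region_model`.
#' @param age_grid Ages in years.
#' @param sex Single value, `"M"` or `"F"`.
#' @param z_level Band half-width in Z units (default 2.6, the extreme-
#'   deviation threshold, a one-sided normal tail below 0.005).
#' @return Data frame: `age`, `mean`, `lower`, `upper`.
#' @export
normative_range <- function(model, age_grid, sex = "M", z_level = 2.6) {
  cov <- data.frame(age = age_grid, sex = rep_len(sex, length(age_grid)))
  pr <- predict_normative(model, cov)
  s <- sqrt(pr$var_f + pr$sigma2_n)
  data.frame(age = age_grid, mean = pr$mean,
             lower = pr$mean - z_level * s, upper = pr$mean + z_level * s)
}

#' Cluster regional lifespan trajectories into increasing/decreasing patterns
#'
#' Evaluates each region's predicted trajectory on an age grid for one sex,
#' standardizes each curve, and k-means-partitions the curves with k = 2.
#' The cluster whose curves rise from start to end (positive mean
#' end-minus-start difference) is labeled `"increasing"`.
#'
#' @param model_set A `normative_model_set`.
#' @param sex `"M"` or `"F"`.
#' @param age_grid Evaluation grid in years.
#' @param seed Seed for k-means restarts.
#' @return Character vector (`"increasing"`/`"decreasing"`) per region, with
#'   the curve matrix in attribute `"curves"`.
#' @export
cluster_trajectories <- function(model_set, sex = "M",
                                 age_grid = seq(20, 64, by = 2), seed = 1) {
  stopifnot(inherits(model_set, "normative_model_set"))
  curves <- t(vapply(model_set$models, function(m) {
    predict_normative(m, data.frame(age = age_grid,
                                    sex = rep_len(sex, length(age_grid))))$mean
  }, numeric(length(age_grid))))
  sds <- apply(curves, 1, stats::sd)
  if (all(sds < 1e-12)) stop("degenerate input: all trajectories are flat")
  std <- (curves - rowMeans(curves)) / pmax(sds, 1e-12)
  if (nrow(unique(std)) < 2) stop("degenerate input: all trajectories identical")
  set.seed(seed)
  km <- stats::kmeans(std, centers = 2, nstart = 10)
  delta <- tapply(std[, ncol(std)] - std[, 1], km$cluster, mean)
  inc_cluster <- as.integer(names(which.max(delta)))
  labels <- ifelse(km$cluster == inc_cluster, "increasing", "decreasing")
  attr(labels, "curves") <- curves
  labels
}

#' Serialize / restore a normative model set as JSON
#'
#' Stores hyperparameters and training data; models are rebuilt (Cholesky
#' recomputed) on read.
#'
#' @param model_set A `normative_model_set`.
#' @param path File path.
#' @return `path` invisibly; reader returns the model set.
#' @export
write_normative_set <- function(model_set, path) {
  stopifnot(inherits(model_set, "normative_model_set"))
  x <- list(
    population_id = model_set$population_id,
    n_regions = model_set$n_regions,
    feature_names = model_set$feature_names,
    models = lapply(model_set$models, function(m) {
      list(theta = as.list(m$theta), y_mean = m$y_mean,
           age_mean = m$age_mean, age_sd = m$age_sd,
           age_range = m$age_range, region_id = m$region_id,
           A_train = as.data.frame(m$A_train), alpha = m$alpha,
           log_marginal_likelihood = m$log_marginal_likelihood)
    })
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_normative_set
#' @export
read_normative_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(x$models, function(m) {
    theta <- unlist(m$theta)[c("sf2", "ell", "wl", "sn2")]
    A <- cbind(age_std = vapply(m$A_train, function(r) r$age_std, numeric(1)),
               sex = vapply(m$A_train, function(r) r$sex, numeric(1)))
    n <- nrow(A)
    K <- .gp_kernel(A, A, theta) + diag(theta[["sn2"]] + 1e-10, n)
    structure(list(
      theta = theta, sigma2_n = theta[["sn2"]],
      A_train = A, y_mean = m$y_mean, alpha = unlist(m$alpha), chol = chol(K),
      age_mean = m$age_mean, age_sd = m$age_sd,
      age_range = unlist(m$age_range),
      log_marginal_likelihood = m$log_marginal_likelihood,
      n_train = n, region_id = m$region_id
    ), class = "gpr_region_model")
  })
  structure(list(models = models,
                 feature_names = unlist(x$feature_names),
                 population_id = x$population_id,
                 n_regions = x$n_regions),
            class = "normative_model_set")
}
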