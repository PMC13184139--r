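# Parametric empirical-Bayes ComBat harmonization of a subjects x regions
# feature matrix: additive site location and multiplicative site scale
# effects are estimated on covariate-standardized data, shrunk across
# regions (normal prior for locations, inverse-gamma for scales), and
# removed while the covariate-explained structure is preserved.

# moment estimators for the inverse-gamma scale prior
.ig_aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
.ig_bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

.eb_postmean <- function(g_hat, g_bar, n, d_star, t2) {
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
}
.eb_postvar <- function(sum2, n, a, b) (0.5 * sum2 + b) / (n / 2 + a - 1)

# iterative conditional EB solution for one site; sdat is regions x subjects
# of standardized data restricted to the site. The convergence measure is the
# canonical relative-change criterion.
.eb_site_solve <- function(sdat, g_hat, d_hat, g_bar, t2, a, b,
                           tol, max_iter) {
  n <- ncol(sdat)
  g_old <- g_hat; d_old <- d_hat
  change <- Inf; count <- 0
  g_new <- g_hat; d_new <- d_hat
  while (change > tol && count < max_iter) {
    g_new <- .eb_postmean(g_hat, g_bar, n, d_old, t2)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- .eb_postvar(sum2, n, a, b)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    count <- count + 1
  }
  list(gamma_star = g_new, delta_star = d_new, iterations = count)
}

# build the covariate part of the design (no intercept; sites absorb it)
.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    mm <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
  } else {
    mm <- as.matrix(covariates)
  }
  stopifnot(nrow(mm) == n)
  mm
}

#' Fit a ComBat harmonization model
#'
#' Standardizes each region by its covariate fit and pooled variance,
#' estimates per-site location (\eqn{\gamma}) and scale (\eqn{\delta^2})
#' effects on the standardized residuals, and shrinks them across regions by
#' parametric empirical Bayes (normal prior for \eqn{\gamma}, inverse-gamma
#' for \eqn{\delta^2}) with the standard iterative conditional scheme.
#'
#' @param features Numeric matrix, subjects x regions.
#' @param site Vector of site identifiers (>= 2 sites, each >= 2 subjects).
#' @param covariates Data frame (e.g. age + sex) or design matrix of
#'   covariates to preserve; may be `NULL`.
#' @param eb Apply empirical-Bayes shrinkage (default `TRUE`). With
#'   `eb = FALSE` the raw per-site estimates are used, which removes site
#'   means/scales exactly (no pooling across regions).
#' @param tol Relative-change convergence tolerance of the EB iteration.
#' @param max_iter Iteration cap.
#' @return Object of class `combat_model` carrying the standardization fit
#'   (covariate coefficients, grand means, pooled variances), the shrunken
#'   `gamma_star` / `delta_star` (sites x regions), EB hyperparameters, and
#'   the site levels.
#' @export
fit_combat <- function(features, site, covariates = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 100) {
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  site <- factor(site)
  if (nlevels(site) < 2) {
    stop("fit_combat requires >= 2 sites; with a single site, skip harmonization")
  }
  if (any(table(site) < 2)) stop("every site needs >= 2 subjects")
  batchmod <- stats::model.matrix(~ -1 + site)
  covmat <- .covariate_matrix(covariates, n)
  design <- cbind(batchmod, covmat)
  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design: covariates confounded with site or each other")
  }
  n_site <- nlevels(site)
  n_per <- as.integer(table(site))

  dat <- t(features)  # regions x subjects
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(n_site), , drop = FALSE])
  var_pooled <- rowMeans((dat - t(design %*% B_hat))^2)
  if (any(var_pooled <= 0)) {
    stop("zero pooled variance in at least one region; data degenerate")
  }
  stand_mean <- matrix(grand_mean, nrow = p, ncol = n)
  if (!is.null(covmat)) {
    stand_mean <- stand_mean +
      t(covmat %*% B_hat[-seq_len(n_site), , drop = FALSE])
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- solve(crossprod(batchmod), t(batchmod) %*% t(s_data))
  delta_hat <- t(vapply(levels(site), function(s) {
    apply(s_data[, site == s, drop = FALSE], 1, stats::var)
  }, numeric(p)))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  a_prior <- apply(delta_hat, 1, .ig_aprior)
  b_prior <- apply(delta_hat, 1, .ig_bprior)

  if (eb) {
    gamma_star <- delta_star <- matrix(NA_real_, n_site, p)
    for (i in seq_len(n_site)) {
      sol <- .eb_site_solve(s_data[, site == levels(site)[i], drop = FALSE],
                            gamma_hat[i, ], delta_hat[i, ],
                            gamma_bar[i], t2[i], a_prior[i], b_prior[i],
                            tol = tol, max_iter = max_iter)
      gamma_star[i, ] <- sol$gamma_star
      delta_star[i, ] <- sol$delta_star
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }
  stopifnot(all(delta_star > 0))

  structure(list(
    site_levels = levels(site),
    n_per_site = n_per,
    B_hat = B_hat,
    n_covariates = if (is.null(covmat)) 0L else ncol(covmat),
    covariate_names = colnames(covmat),
    grand_mean = as.numeric(grand_mean),
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    eb = eb,
    priors = list(gamma_bar = gamma_bar, t2 = t2,
                  a_prior = a_prior, b_prior = b_prior),
    feature_names = colnames(features)
  ), class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Standardizes new data with the stored covariate fit and pooled variance,
#' removes the shrunken site location/scale, and restores the covariate fit:
#' \eqn{y^* = \sqrt{v_r}\,(y_{std} - \gamma^*_{sr})/\delta^*_{sr} + \hat y_{cov}}.
#'
#' @param model A `combat_model`.
#' @param features Subjects x regions matrix.
#' @param site Site ids; every value must be a site seen at fit time.
#' @param covariates Covariates matching the fit-time design.
#' @return Harmonized subjects x regions matrix.
#' @export
apply_combat <- function(model, features, site, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  site <- as.character(site)
  unseen <- setdiff(unique(site), model$site_levels)
  if (length(unseen) > 0) {
    stop("apply_combat: site(s) not present in the fitted model: ",
         paste(unseen, collapse = ", "))
  }
  covmat <- .covariate_matrix(covariates, n)
  n_cov <- if (is.null(covmat)) 0L else ncol(covmat)
  if (n_cov != model$n_covariates) {
    stop("covariates do not match the fitted model")
  }
  n_site <- length(model$site_levels)
  dat <- t(features)
  stand_mean <- matrix(model$grand_mean, nrow = p, ncol = n)
  if (n_cov > 0) {
    stand_mean <- stand_mean +
      t(covmat %*% model$B_hat[-seq_len(n_site), , drop = FALSE])
  }
  s_data <- (dat - stand_mean) / sqrt(model$var_pooled)
  si <- match(site, model$site_levels)
  adj <- (s_data - t(model$gamma_star[si, , drop = FALSE])) /
    sqrt(t(model$delta_star[si, , drop = FALSE]))
  out <- t(adj * sqrt(model$var_pooled) + stand_mean)
  dimnames(out) <- dimnames(features)
  out
}

#' One-call ComBat harmonization
#'
#' @inheritParams fit_combat
#' @return Harmonized subjects x regions matrix with the fitted model in
#'   attribute `"model"`.
#' @export
combat_harmonize <- function(features, site, covariates = NULL, eb = TRUE,
                             tol = 1e-6, max_iter = 100) {
  model <- fit_combat(features, site, covariates, eb = eb, tol = tol,
                      max_iter = max_iter)
  out <- apply_combat(model, features, site, covariates)
  attr(out, "model") <- model
  out
}

#' Serialize / restore a ComBat model as JSON
#'
#' @param model A `combat_model`.
#' @param path File path.
#' @return `path` invisibly; `read_combat_model` returns the model.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  x <- unclass(model)
  x$B_hat <- as.data.frame(x$B_hat)
  x$gamma_star <- as.data.frame(x$gamma_star)
  x$delta_star <- as.data.frame(x$delta_star)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$B_hat <- as.matrix(x$B_hat)
  x$gamma_star <- as.matrix(x$gamma_star)
  x$delta_star <- as.matrix(x$delta_star)
  x$n_per_site <- as.integer(x$n_per_site)
  x$n_covariates <- as.integer(x$n_covariates)
  class(x) <- "combat_model"
  x
}
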