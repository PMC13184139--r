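# Deviation-map summaries (indices, extreme counts, overlap maps,
# prevalences) and the comparison statistics used to characterize groups:
# t-tests with Cohen's d, one-way ANOVA with partial eta^2, ANCOVA with a
# factor x covariate interaction, Cramer's V, Pearson correlation, and
# Benjamini-Hochberg FDR adjustment.

#' Per-subject deviation indices and extreme-deviation counts
#'
#' The overall index is the mean Z over regions; the positive index the mean
#' of `max(Z, 0)` and the negative index the mean of `min(Z, 0)` — so
#' `overall = positive + negative` holds exactly. Extreme counts use the
#' strict inequality `|Z| > threshold` (a boundary value is not extreme).
#'
#' @param Z Subjects x regions deviation matrix.
#' @param threshold Extreme-deviation threshold (default 2.6, one-sided
#'   normal tail below 0.005).
#' @return Data frame with one row per subject: `overall_index`,
#'   `positive_index`, `negative_index`, `extreme_total`, `extreme_positive`,
#'   `extreme_negative`.
#' @export
deviation_indices <- function(Z, threshold = 2.6) {
  Z <- as.matrix(Z)
  stopifnot(all(is.finite(Z)), threshold > 0)
  data.frame(
    subject_id = rownames(Z) %||% seq_len(nrow(Z)),
    overall_index = rowMeans(Z),
    positive_index = rowMeans(pmax(Z, 0)),
    negative_index = rowMeans(pmin(Z, 0)),
    extreme_positive = rowSums(Z > threshold),
    extreme_negative = rowSums(Z < -threshold),
    extreme_total = rowSums(abs(Z) > threshold),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-region spatial overlap of extreme deviations
#'
#' For each region, the percentage of subjects whose Z exceeds the threshold
#' in the positive / negative direction.
#'
#' @inheritParams deviation_indices
#' @return Data frame: `region`, `percent_positive`, `percent_negative`.
#' @export
overlap_map <- function(Z, threshold = 2.6) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) >= 1)
  data.frame(
    region = colnames(Z) %||% seq_len(ncol(Z)),
    percent_positive = 100 * colMeans(Z > threshold),
    percent_negative = 100 * colMeans(Z < -threshold),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cohort-level extreme-deviation prevalences
#'
#' Percentages of subjects with at least one extreme deviation (any,
#' positive, negative) and of regions with at least one extreme subject.
#'
#' @inheritParams deviation_indices
#' @return Named list of percentages.
#' @export
prevalence_stats <- function(Z, threshold = 2.6) {
  Z <- as.matrix(Z)
  pos <- Z > threshold; neg <- Z < -threshold
  list(
    subjects_any = 100 * mean(rowSums(pos | neg) > 0),
    subjects_positive = 100 * mean(rowSums(pos) > 0),
    subjects_negative = 100 * mean(rowSums(neg) > 0),
    regions_any = 100 * mean(colSums(pos | neg) > 0),
    regions_positive = 100 * mean(colSums(pos) > 0),
    regions_negative = 100 * mean(colSums(neg) > 0)
  )
}

#' Two-group comparison with Cohen's d
#'
#' Welch's t-test by default (site-driven variance heterogeneity), with the
#' conventional pooled-SD Cohen's d:
#' \eqn{d = (\bar x_A - \bar x_B)/s_p}, \eqn{s_p^2} the n-1-weighted pooled
#' variance.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List of class `comparison_result`: `statistic`, `p`, `effect_size`
#'   (`d`), `effect_kind`, group sizes.
#' @export
compare_groups_t <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(
    statistic = unname(tt$statistic), p = tt$p.value,
    effect_size = (mean(a) - mean(b)) / sqrt(sp2), effect_kind = "cohens_d",
    n = c(length(a), length(b))
  ), class = "comparison_result")
}

#' One-way ANOVA with partial eta squared
#'
#' F-test across >= 2 groups; partial
#' \eqn{\eta^2 = SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param values Numeric vector.
#' @param group Group labels (>= 2 levels).
#' @return `comparison_result` with the F statistic, p, and partial eta^2.
#' @export
anova_partial_eta <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (length(values) <= nlevels(group)) stop("need total n > number of groups")
  if (stats::var(values) <= 0) stop("degenerate outcome variance")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  ss_eff <- tab[["Sum Sq"]][1]; ss_err <- tab[["Sum Sq"]][2]
  structure(list(
    statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
    effect_size = ss_eff / (ss_eff + ss_err), effect_kind = "partial_eta2",
    n = as.integer(table(group))
  ), class = "comparison_result")
}

#' ANCOVA with a factor x covariate interaction
#'
#' Fits `outcome ~ factor * covariate` and reports type-III tests with
#' partial eta^2 for the factor main effect, the covariate main effect, and
#' the interaction (sum-to-zero factor contrasts, as type-III requires).
#'
#' @param outcome Numeric outcome.
#' @param factor_var Grouping factor (e.g. subtype).
#' @param covariate Numeric covariate (e.g. illness duration).
#' @return Data frame with one row per term: `term`, `F`, `p`, `partial_eta2`.
#' @export
ancova_interaction <- function(outcome, factor_var, covariate) {
  f <- factor(factor_var)
  if (nlevels(f) < 2) stop("factor needs >= 2 levels")
  df <- data.frame(y = outcome, f = f, x = covariate)
  fit <- stats::lm(y ~ f * x, data = df,
                   contrasts = list(f = "contr.sum"))
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) stop("collinear design in ANCOVA")
  tab <- car::Anova(fit, type = 3)
  terms <- c("f", "x", "f:x")
  ss_err <- tab["Residuals", "Sum Sq"]
  out <- data.frame(
    term = c("factor", "covariate", "interaction"),
    F = tab[terms, "F value"],
    p = tab[terms, "Pr(>F)"],
    partial_eta2 = tab[terms, "Sum Sq"] / (tab[terms, "Sum Sq"] + ss_err),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  out
}

#' Cramer's V for a contingency table
#'
#' \eqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}} with the uncorrected
#' Pearson chi-square.
#'
#' @param tab Contingency table or matrix of non-negative counts, >= 2x2.
#' @return `comparison_result` with the chi-square statistic, p, and V.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0) stop("need a non-empty non-negative table")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(ct$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
  structure(list(
    statistic = unname(ct$statistic), p = ct$p.value,
    effect_size = v, effect_kind = "cramers_v", n = sum(tab)
  ), class = "comparison_result")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @return `comparison_result` with r as the effect size.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(
    statistic = unname(ct$statistic), p = ct$p.value,
    effect_size = unname(ct$estimate), effect_kind = "pearson_r",
    n = length(x)
  ), class = "comparison_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted q-values (same length and order).
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g, %s = %.4g (n = %s)\n",
              x$statistic, x$p, x$effect_kind, x$effect_size,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Compare a subgroup's extreme-deviation overlap map against a reference cohort
#'
#' Paired region-wise comparison of overlap percentages (e.g. one subtype
#' versus all patients): per direction, the per-region percentages are
#' compared by a paired t-test with the paired Cohen's d
#' (mean difference / SD of differences), and the subgroup's range of
#' nonzero overlap percentages is reported.
#'
#' @param Z_sub Deviation map of the subgroup (subjects x regions).
#' @param Z_ref Deviation map of the reference cohort over the same regions.
#' @param threshold Extreme-deviation threshold.
#' @return List with one `comparison_result` per direction (`positive`,
#'   `negative`) plus the subgroup overlap ranges.
#' @export
overlap_comparison <- function(Z_sub, Z_ref, threshold = 2.6) {
  om_s <- overlap_map(Z_sub, threshold)
  om_r <- overlap_map(Z_ref, threshold)
  paired <- function(a, b) {
    d <- a - b
    if (stats::sd(d) == 0) stop("degenerate overlap differences")
    tt <- stats::t.test(a, b, paired = TRUE)
    structure(list(
      statistic = unname(tt$statistic), p = tt$p.value,
      effect_size = mean(d) / stats::sd(d), effect_kind = "cohens_d_paired",
      n = length(d)
    ), class = "comparison_result")
  }
  rng <- function(x) range(x[x > 0])
  list(
    positive = paired(om_s$percent_positive, om_r$percent_positive),
    negative = paired(om_s$percent_negative, om_r$percent_negative),
    subgroup_range_positive = rng(om_s$percent_positive),
    subgroup_range_negative = rng(om_s$percent_negative)
  )
}

#' Region-wise group comparison table
#'
#' Welch t-test with Cohen's d for every region of a deviation (or feature)
#' matrix between two groups, with BH-FDR adjusted q-values.
#'
#' @param Z Subjects x regions matrix.
#' @param group Two-level grouping vector over rows.
#' @return Tidy data frame: one row per region with `t`, `p`, `q`, `d`.
#' @export
regionwise_t_table <- function(Z, group) {
  Z <- as.matrix(Z)
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  res <- lapply(seq_len(ncol(Z)), function(r) {
    cr <- compare_groups_t(Z[g == lv[1], r], Z[g == lv[2], r])
    data.frame(region = colnames(Z)[r] %||% r, t = cr$statistic,
               p = cr$p, d = cr$effect_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}
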