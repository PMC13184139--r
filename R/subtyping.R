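# Unsupervised subtype discovery on deviation maps: k-means (k-means++
# multi-restart) with majority-vote selection of k over a battery of cluster
# validity indices, network-level aggregation, label alignment by optimal
# cluster-name assignment, adjusted Rand index, and stability validation
# (leave-one-site-out, site filters, subgroup reruns).

# ---- k-means core -----------------------------------------------------------

# k-means++ seeding
.kmpp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Cluster subjects by k-means on deviation maps
#'
#' Euclidean k-means with k-means++ initialization; best of `n_restarts`
#' runs by total within-cluster sum of squares.
#'
#' @param Z Subjects x regions matrix.
#' @param k Number of clusters (>= 2, <= n).
#' @param n_restarts Restarts (default 50).
#' @param seed Integer seed.
#' @return Object of class `subtype_result`: `labels`, `centers`, `k`,
#'   `tot_withinss`, Euclidean within/between distance summaries, `seed`,
#'   `n_restarts`.
#' @export
cluster_subjects <- function(Z, k, n_restarts = 50, seed = 1) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of subjects")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .kmpp_init(Z, k)
    km <- tryCatch(stats::kmeans(Z, centers = init, iter.max = 100),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < k) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts (empty clusters?)")
  centers <- best$centers
  dcent <- as.matrix(stats::dist(centers))
  within_mean <- vapply(seq_len(k), function(c) {
    pts <- Z[best$cluster == c, , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(centers[c, ], nrow(pts), ncol(Z),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  structure(list(
    labels = stats::setNames(best$cluster, rownames(Z)),
    centers = centers, k = k,
    tot_withinss = best$tot.withinss,
    within_mean_dist = within_mean,
    between_center_dist = dcent,
    seed = seed, n_restarts = n_restarts
  ), class = "subtype_result")
}

# ---- validity indices -------------------------------------------------------

# Per-k quantities shared by the indices. D is the full distance matrix.
.index_battery_names <- c("silhouette", "calinski_harabasz", "davies_bouldin",
                          "dunn", "gap", "hartigan", "krzanowski_lai",
                          "c_index", "mcclain_rao", "ratkowsky_lance",
                          "ball_hall")

.mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    din <- D[i, labels == own]
    a <- if (length(din) > 1) sum(din) / (length(din) - 1) else 0
    b <- min(vapply(setdiff(ks, own), function(c) mean(D[i, labels == c]),
                    numeric(1)))
    s[i] <- if (length(din) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

.davies_bouldin <- function(Z, labels, centers) {
  k <- nrow(centers)
  S <- vapply(seq_len(k), function(c) {
    pts <- Z[labels == c, , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(centers[c, ], nrow(pts), ncol(Z),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centers))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (S[i] + S[j]) / M[i, j],
               numeric(1)))
  }, numeric(1)))
}

.dunn <- function(D, labels) {
  ks <- sort(unique(labels))
  min_between <- Inf; max_diam <- 0
  for (a in ks) {
    ia <- which(labels == a)
    max_diam <- max(max_diam, max(D[ia, ia]))
    for (b in ks[ks > a]) {
      min_between <- min(min_between, min(D[ia, labels == b]))
    }
  }
  min_between / max_diam
}

.c_index <- function(D, labels) {
  dv <- D[upper.tri(D)]
  pair_same <- outer(labels, labels, "==")[upper.tri(D)]
  Sw <- sum(dv[pair_same]); Nw <- sum(pair_same)
  ds <- sort(dv)
  Smin <- sum(ds[seq_len(Nw)])
  Smax <- sum(ds[seq.int(length(ds) - Nw + 1, length(ds))])
  (Sw - Smin) / (Smax - Smin)
}

.mcclain_rao <- function(D, labels) {
  dv <- D[upper.tri(D)]
  pair_same <- outer(labels, labels, "==")[upper.tri(D)]
  (mean(dv[pair_same])) / (mean(dv[!pair_same]))
}

.ratkowsky_lance <- function(Z, labels, k) {
  overall <- colMeans(Z)
  tssj <- colSums((Z - matrix(overall, nrow(Z), ncol(Z), byrow = TRUE))^2)
  bgssj <- numeric(ncol(Z))
  for (c in sort(unique(labels))) {
    nc <- sum(labels == c)
    mc <- colMeans(Z[labels == c, , drop = FALSE])
    bgssj <- bgssj + nc * (mc - overall)^2
  }
  mean(sqrt(bgssj / tssj)) / sqrt(k)
}

# uniform reference draws over the per-feature ranges for the gap statistic
.gap_reference_w <- function(Z, k, B, seed) {
  rngs <- apply(Z, 2, range)
  vapply(seq_len(B), function(b) {
    set.seed(seed + 100003L * b + k)
    ref <- matrix(stats::runif(length(Z), rep(rngs[1, ], each = nrow(Z)),
                               rep(rngs[2, ], each = nrow(Z))),
                  nrow = nrow(Z))
    km <- cluster_subjects(ref, k, n_restarts = 3, seed = seed + b)
    log(km$tot_withinss)
  }, numeric(1))
}

#' Majority-vote selection of the number of clusters
#'
#' Evaluates k-means solutions over `k_range` with a battery of validity
#' indices; each index votes for the k its own optimum rule prefers and the
#' winner is the mode (ties broken toward the smallest k). Optimum rules:
#' silhouette, Calinski-Harabasz, Dunn, Krzanowski-Lai and Ratkowsky-Lance
#' are maximized; Davies-Bouldin, C-index and McClain-Rao minimized; the gap
#' statistic uses the one-standard-error rule (smallest k with
#' `Gap(k) >= Gap(k+1) - s(k+1)`); Hartigan picks the smallest k with
#' `H(k) <= 10`; Ball-Hall picks the largest successive drop of `W_k / k`.
#'
#' @param Z Subjects x regions matrix (n > max(k_range)).
#' @param k_range Candidate k values (default 2:8).
#' @param index_battery Subset of the index names to use.
#' @param seed Seed for k-means restarts and gap references.
#' @param n_restarts Restarts per k-means solution.
#' @param gap_B Reference draws for the gap statistic.
#' @return Object of class `k_selection_report`: per-index chosen k, vote
#'   tally, winning k, and the per-k index values.
#' @export
select_k <- function(Z, k_range = 2:8, index_battery = .index_battery_names,
                     seed = 1, n_restarts = 20, gap_B = 10) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n <= max(k_range)) stop("need more subjects than max(k_range)")
  index_battery <- match.arg(index_battery, .index_battery_names,
                             several.ok = TRUE)
  if (length(index_battery) == 0) stop("empty index battery")
  ks_all <- seq(min(k_range), max(k_range) + 1L)  # +1 for Hartigan/KL/gap
  tss <- sum((Z - matrix(colMeans(Z), n, ncol(Z), byrow = TRUE))^2)
  sols <- lapply(ks_all, function(k) {
    cluster_subjects(Z, k, n_restarts = n_restarts, seed = seed + k)
  })
  names(sols) <- ks_all
  W <- vapply(sols, `[[`, numeric(1), "tot_withinss")
  W_by_k <- c(stats::setNames(tss, "1"), W)  # includes k = 1
  D <- as.matrix(stats::dist(Z))
  p <- ncol(Z)

  in_range <- as.character(k_range)
  val <- function(f) vapply(in_range, function(kc) f(sols[[kc]]), numeric(1))

  values <- list()
  if ("silhouette" %in% index_battery) {
    values$silhouette <- val(function(s) .mean_silhouette(D, s$labels))
  }
  if ("calinski_harabasz" %in% index_battery) {
    values$calinski_harabasz <- val(function(s) {
      ((tss - s$tot_withinss) / (s$k - 1)) / (s$tot_withinss / (n - s$k))
    })
  }
  if ("davies_bouldin" %in% index_battery) {
    values$davies_bouldin <- val(function(s) .davies_bouldin(Z, s$labels, s$centers))
  }
  if ("dunn" %in% index_battery) {
    values$dunn <- val(function(s) .dunn(D, s$labels))
  }
  if ("gap" %in% index_battery) {
    logW_ref <- lapply(ks_all, function(k) .gap_reference_w(Z, k, gap_B, seed))
    gap_all <- vapply(seq_along(ks_all), function(i) {
      mean(logW_ref[[i]]) - log(W[i])
    }, numeric(1))
    s_all <- vapply(logW_ref, function(lw) {
      stats::sd(lw) * sqrt(1 + 1 / length(lw))
    }, numeric(1))
    values$gap <- stats::setNames(gap_all[seq_along(k_range)], in_range)
    attr(values$gap, "se") <- s_all
    attr(values$gap, "gap_all") <- gap_all
  }
  if ("hartigan" %in% index_battery) {
    values$hartigan <- vapply(seq_along(k_range), function(i) {
      k <- k_range[i]
      (W_by_k[as.character(k)] / W_by_k[as.character(k + 1)] - 1) * (n - k - 1)
    }, numeric(1))
    names(values$hartigan) <- in_range
  }
  if ("krzanowski_lai" %in% index_battery) {
    diff_k <- function(k) {
      (k - 1)^(2 / p) * W_by_k[as.character(k - 1)] -
        k^(2 / p) * W_by_k[as.character(k)]
    }
    values$krzanowski_lai <- vapply(k_range, function(k) {
      abs(diff_k(k)) / abs(diff_k(k + 1))
    }, numeric(1))
    names(values$krzanowski_lai) <- in_range
  }
  if ("c_index" %in% index_battery) {
    values$c_index <- val(function(s) .c_index(D, s$labels))
  }
  if ("mcclain_rao" %in% index_battery) {
    values$mcclain_rao <- val(function(s) .mcclain_rao(D, s$labels))
  }
  if ("ratkowsky_lance" %in% index_battery) {
    values$ratkowsky_lance <- val(function(s) .ratkowsky_lance(Z, s$labels, s$k))
  }
  if ("ball_hall" %in% index_battery) {
    bh <- W_by_k[as.character(c(min(k_range) - 1, k_range))] /
      c(min(k_range) - 1, k_range)
    values$ball_hall <- stats::setNames(
      bh[-length(bh)] - bh[-1], in_range)  # successive drop ending at each k
  }

  pick <- function(name, v) {
    switch(name,
      silhouette = , calinski_harabasz = , dunn = ,
      krzanowski_lai = , ratkowsky_lance = , ball_hall =
        k_range[which.max(v)],
      davies_bouldin = , c_index = , mcclain_rao = k_range[which.min(v)],
      hartigan = {
        ok <- which(v <= 10)
        if (length(ok) > 0) k_range[ok[1]] else k_range[which.min(v)]
      },
      gap = {
        g <- attr(v, "gap_all"); s <- attr(v, "se")
        sel <- NA
        for (i in seq_along(k_range)) {
          if (g[i] >= g[i + 1] - s[i + 1]) { sel <- k_range[i]; break }
        }
        if (is.na(sel)) k_range[which.max(v)] else sel
      }
    )
  }
  chosen <- vapply(names(values), function(nm) pick(nm, values[[nm]]),
                   numeric(1))
  tally <- table(factor(chosen, levels = k_range))
  winners <- as.integer(names(tally)[tally == max(tally)])
  structure(list(
    k_range = k_range,
    chosen_k = chosen,
    tally = tally,
    k = min(winners),   # tie-break toward the smallest k
    index_values = values
  ), class = "k_selection_report")
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat("k selection over", paste(range(x$k_range), collapse = ".."),
      "-> k =", x$k, "\n")
  print(x$tally)
  invisible(x)
}

# ---- aggregation, alignment, validation -------------------------------------

#' Aggregate a deviation map to network level
#'
#' @param Z Subjects x regions matrix.
#' @param region_networks Character vector (one network per region, in column
#'   order) or a `region_specs` data frame.
#' @return Subjects x networks matrix of mean member-region deviations.
#' @export
network_aggregate <- function(Z, region_networks) {
  Z <- as.matrix(Z)
  if (inherits(region_networks, "region_specs")) {
    region_networks <- region_networks$network
  }
  if (length(region_networks) != ncol(Z) || anyNA(region_networks)) {
    stop("region-to-network map must cover every region")
  }
  nets <- unique(region_networks)
  out <- vapply(nets, function(nw) {
    rowMeans(Z[, region_networks == nw, drop = FALSE])
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, nets))
  rownames(out) <- rownames(Z)
  out
}

# all permutations of 1..k (k small)
.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Align cluster labels to a reference by optimal cluster-name assignment
#'
#' Finds the permutation of the candidate's cluster names that maximizes
#' agreement with the reference (exact search over the confusion matrix) and
#' reports the overlap rate (percent of subjects agreeing after alignment).
#' Named vectors are matched on names; unnamed vectors must align by
#' position.
#'
#' @param reference,candidate Label vectors.
#' @return List: `labels` (aligned candidate), `overlap` (percent),
#'   `permutation`.
#' @export
align_labels <- function(reference, candidate) {
  if (!is.null(names(reference)) && !is.null(names(candidate))) {
    shared <- intersect(names(reference), names(candidate))
    if (length(shared) == 0) stop("disjoint subject sets")
    ref <- reference[shared]; cand <- candidate[shared]
  } else {
    if (length(reference) != length(candidate)) {
      stop("unnamed label vectors must have equal length")
    }
    ref <- reference; cand <- candidate
  }
  rl <- sort(unique(c(ref, cand)))
  k <- length(rl)
  ri <- match(ref, rl); ci <- match(cand, rl)
  conf <- matrix(0L, k, k)
  for (i in seq_along(ri)) conf[ri[i], ci[i]] <- conf[ri[i], ci[i]] + 1L
  perms <- .permutations(k)
  agree <- vapply(perms, function(p) sum(conf[cbind(p, seq_len(k))]),
                  numeric(1))
  best <- perms[[which.max(agree)]]
  aligned <- rl[best][ci]
  names(aligned) <- names(cand)
  list(labels = aligned,
       overlap = 100 * max(agree) / length(ref),
       permutation = stats::setNames(rl[best], rl))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same subjects; 1 = identical, ~0 = chance.
#'
#' @param labels_a,labels_b Label vectors of equal length >= 2.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 subjects")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Drop subjects from undersized sites
#'
#' @param cohort Data frame with a `site_id` column.
#' @param min_site_n Minimum site size; sites below it are removed.
#' @return Filtered cohort; dropped counts reported via `message()`.
#' @export
site_filters <- function(cohort, min_site_n) {
  counts <- table(cohort$site_id)
  drop <- names(counts)[counts < min_site_n]
  kept <- !(cohort$site_id %in% drop)
  if (!any(kept)) stop("site filter removed every subject")
  if (length(drop) > 0) {
    message(sprintf("site_filters: dropped %d site(s), %d subject(s)",
                    length(drop), sum(!kept)))
  }
  cohort[kept, , drop = FALSE]
}

#' Leave-one-site-out clustering stability
#'
#' For each site, reclusters all remaining subjects with the same k and
#' seed, aligns the fold's labels to the primary labels on the shared
#' subjects, and records the overlap rate. Folds in which k-means cannot
#' produce k non-empty clusters are recorded as failed, not dropped
#' silently.
#'
#' @param Z Subjects x regions matrix (rownames = subject ids).
#' @param sites Site id per subject.
#' @param k Number of clusters.
#' @param seed Seed for all reclustering.
#' @param primary Optional `subtype_result` for the full cohort; computed if
#'   missing.
#' @param n_restarts Restarts per k-means.
#' @return Object of class `validation_report`: per-site table (`site`,
#'   `n_held_out`, `overlap`, `ari`, `failed`), `min_overlap`,
#'   `mean_overlap`.
#' @export
leave_one_site_out <- function(Z, sites, k, seed = 1, primary = NULL,
                               n_restarts = 50) {
  Z <- as.matrix(Z)
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("S%05d", seq_len(nrow(Z)))
  sites <- as.character(sites)
  if (length(unique(sites)) < 3) stop("need >= 3 sites")
  if (is.null(primary)) primary <- cluster_subjects(Z, k, n_restarts, seed)
  ref <- primary$labels
  rows <- lapply(sort(unique(sites)), function(s) {
    keep <- sites != s
    res <- tryCatch(
      cluster_subjects(Z[keep, , drop = FALSE], k, n_restarts, seed),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(site = s, n_held_out = sum(!keep), overlap = NA_real_,
                        ari = NA_real_, failed = TRUE))
    }
    al <- align_labels(ref, res$labels)
    shared <- names(al$labels)
    data.frame(site = s, n_held_out = sum(!keep), overlap = al$overlap,
               ari = adjusted_rand(ref[shared], al$labels),
               failed = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(per_site = tab,
                 min_overlap = min(tab$overlap, na.rm = TRUE),
                 mean_overlap = mean(tab$overlap, na.rm = TRUE),
                 n_failed = sum(tab$failed), k = k, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("leave-one-site-out (k = %d): min overlap %.2f%%, mean %.2f%%",
              x$k, x$min_overlap, x$mean_overlap))
  if (x$n_failed > 0) cat(sprintf(" [%d failed fold(s)]", x$n_failed))
  cat("\n")
  invisible(x)
}

#' Subgroup reclustering validation
#'
#' Reclusters within demographic and clinical subgroups (male, female,
#' young/old at the cohort median age, FEDN, recurrent, medicated) and
#' reports the overlap rate and ARI against the primary labels restricted to
#' each subgroup. Subgroups with too few subjects are skipped with a
#' warning.
#'
#' @param Z Subjects x regions matrix (rownames = subject ids).
#' @param cohort Cohort data frame aligned with the rows of `Z` (columns
#'   `sex`, `age`, `episode_status`, `medicated`).
#' @param primary A `subtype_result` on the full cohort.
#' @param groupings Character vector of subgroups to run.
#' @param seed,n_restarts Clustering settings.
#' @return `validation_report`-classed list with a per-subgroup table.
#' @export
subgroup_validation <- function(Z, cohort, primary,
                                groupings = c("male", "female", "young", "old",
                                              "FEDN", "recurrent", "medicated"),
                                seed = 1, n_restarts = 50) {
  Z <- as.matrix(Z)
  if (is.null(rownames(Z))) rownames(Z) <- cohort$subject_id
  med_age <- stats::median(cohort$age)
  sel <- list(
    male = cohort$sex == "M", female = cohort$sex == "F",
    young = cohort$age < med_age, old = cohort$age >= med_age,
    FEDN = cohort$episode_status == "FEDN",
    recurrent = cohort$episode_status == "recurrent",
    medicated = !is.na(cohort$medicated) & cohort$medicated
  )
  k <- primary$k
  rows <- lapply(groupings, function(g) {
    keep <- which(!is.na(sel[[g]]) & sel[[g]])
    if (length(keep) <= k) {
      warning(sprintf("subgroup '%s' too small (n = %d); skipped", g,
                      length(keep)))
      return(NULL)
    }
    res <- cluster_subjects(Z[keep, , drop = FALSE], k, n_restarts, seed)
    al <- align_labels(primary$labels, res$labels)
    shared <- names(al$labels)
    data.frame(subgroup = g, n = length(keep), overlap = al$overlap,
               ari = adjusted_rand(primary$labels[shared], al$labels),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(per_subgroup = tab,
                 min_overlap = min(tab$overlap),
                 mean_overlap = mean(tab$overlap),
                 k = k, seed = seed),
            class = "validation_report")
}
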