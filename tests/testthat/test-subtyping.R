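planted_two_clusters <- function(n = 60, p = 8, sep = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n)
  x[seq_len(n / 2), 1] <- x[seq_len(n / 2), 1] + sep
  rownames(x) <- sprintf("s%03d", seq_len(n))
  list(x = x, truth = rep(1:2, each = n / 2))
}

test_that("k-means separates well-separated clouds and is consistent on duplicates", {
  fx <- planted_two_clusters(sep = 20, seed = 2)
  res <- cluster_subjects(fx$x, 2, n_restarts = 10, seed = 3)
  expect_equal(adjusted_rand(res$labels, fx$truth), 1)
  expect_equal(res$between_center_dist[1, 2], 20, tolerance = 1)
  expect_error(cluster_subjects(fx$x, 1), "k must be")
  expect_error(cluster_subjects(fx$x[1:3, ], 5), "exceed")
  # duplicated subjects land in the same cluster
  dup <- rbind(fx$x, fx$x)
  rownames(dup) <- sprintf("d%03d", seq_len(nrow(dup)))
  resd <- cluster_subjects(dup, 2, n_restarts = 10, seed = 4)
  expect_equal(unname(resd$labels[1:60]), unname(resd$labels[61:120]))
})

test_that("k-means with restarts attains the exhaustive 2-partition optimum on 8 points", {
  set.seed(5)
  x <- matrix(stats::rnorm(16), 8, 2)
  res <- cluster_subjects(x, 2, n_restarts = 50, seed = 6)
  # brute force over all 2^7 - 1 bipartitions
  best <- Inf
  for (code in 1:127) {
    grp <- as.integer(intToBits(code))[1:8]
    if (length(unique(grp)) < 2) next
    wss <- 0
    for (g in 0:1) {
      pts <- x[grp == g, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum((pts - matrix(ctr, nrow(pts), 2, byrow = TRUE))^2)
    }
    best <- min(best, wss)
  }
  expect_equal(res$tot_withinss, best, tolerance = 1e-6)
})

test_that("majority vote selects k = 2 on well-separated planted clusters", {
  fx <- planted_two_clusters(n = 80, p = 10, sep = 8, seed = 7)
  rep <- select_k(fx$x, k_range = 2:5, seed = 8, n_restarts = 10, gap_B = 5)
  expect_equal(rep$k, 2)
  expect_gte(sum(rep$chosen_k == 2), length(rep$chosen_k) / 2)
  expect_true(all(rep$chosen_k >= 2 & rep$chosen_k <= 5))
  expect_equal(sum(rep$tally), length(rep$chosen_k))
  expect_error(select_k(fx$x, index_battery = character(0)), "")
  expect_error(select_k(fx$x[1:4, ], k_range = 2:8), "more subjects")
})

test_that("a reduced index battery votes and ties break toward the smallest k", {
  fx <- planted_two_clusters(n = 40, p = 6, sep = 6, seed = 9)
  rep <- select_k(fx$x, k_range = 2:4, seed = 10, n_restarts = 5,
                  index_battery = c("silhouette", "calinski_harabasz"))
  expect_equal(sum(rep$tally), 2)
  expect_true(rep$k %in% 2:4)
  # with a tied tally the smallest candidate wins by construction
  tally <- table(factor(c(2, 3), levels = 2:4))
  winners <- as.integer(names(tally)[tally == max(tally)])
  expect_equal(min(winners), 2)
})

test_that("network aggregation averages member regions exactly", {
  Z <- matrix(0, 2, 4)
  Z[1, ] <- c(1, 3, 2, 2)
  nets <- c("A", "A", "B", "B")
  out <- network_aggregate(Z, nets)
  expect_equal(unname(out[1, "A"]), 2)
  expect_equal(unname(out[1, "B"]), 2)
  expect_true(all(network_aggregate(matrix(0, 3, 4), nets) == 0))
  expect_error(network_aggregate(Z, c("A", "A", "B")), "every region")
  # group-by mean oracle on a random fixture
  set.seed(11)
  rs <- test_regions()
  Zr <- matrix(stats::rnorm(5 * 246), 5)
  agg <- network_aggregate(Zr, rs)
  for (nw in network_labels()) {
    expect_equal(agg[, nw], rowMeans(Zr[, rs$network == nw]), tolerance = 1e-12)
  }
})

test_that("label alignment maximizes agreement over cluster renamings", {
  expect_equal(align_labels(c(1, 1, 2, 2), c(1, 1, 2, 2))$overlap, 100)
  expect_equal(align_labels(c(1, 1, 2, 2), c(2, 2, 1, 1))$overlap, 100)
  al <- align_labels(c(1, 1, 1, 2), c(1, 1, 2, 2))
  expect_equal(al$overlap, 75)
  # symmetric in its arguments and invariant to renaming
  expect_equal(align_labels(c(1, 1, 2, 2, 3), c(3, 3, 1, 2, 2))$overlap,
               align_labels(c(3, 3, 1, 2, 2), c(1, 1, 2, 2, 3))$overlap)
  # named vectors align on the shared subjects
  a <- stats::setNames(c(1, 1, 2, 2), c("s1", "s2", "s3", "s4"))
  b <- stats::setNames(c(2, 2, 1), c("s2", "s1", "s3"))
  expect_equal(align_labels(a, b)$overlap, 100)
  expect_error(align_labels(a, stats::setNames(1:2, c("x1", "x2"))), "disjoint")
  expect_error(align_labels(c(1, 2), c(1, 2, 1)), "equal length")
})

test_that("adjusted Rand matches brute-force pair counting and the reference implementation", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_error(adjusted_rand(1:3, 1:4), "length mismatch")

  ari_bruteforce <- function(a, b) {
    n <- length(a)
    pairs <- utils::combn(n, 2)
    same_a <- a[pairs[1, ]] == a[pairs[2, ]]
    same_b <- b[pairs[1, ]] == b[pairs[2, ]]
    n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
    np <- ncol(pairs)
    ri <- (n11 + n00) / np
    # expected index from the marginals
    pa <- sum(same_a) / np; pb <- sum(same_b) / np
    e <- pa * pb + (1 - pa) * (1 - pb)
    (ri - e) / (1 - e)
  }
  expect_equal(adjusted_rand(c(1, 1, 1, 2), c(1, 1, 2, 2)),
               ari_bruteforce(c(1, 1, 1, 2), c(1, 1, 2, 2)), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_equal(adjusted_rand(a, b), ari_bruteforce(a, b), tolerance = 1e-12)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("site filtering drops undersized sites and nothing else", {
  co <- data.frame(subject_id = sprintf("s%02d", 1:25),
                   site_id = rep(c("a", "b", "c"), c(12, 9, 4)))
  expect_message(out <- site_filters(co, 10), "dropped 2 site")
  expect_equal(unique(out$site_id), "a")
  expect_identical(site_filters(co, 0), co)
  expect_error(site_filters(co, 100), "every subject")
  # counts after filtering equal a brute-force tally
  keep <- names(which(table(co$site_id) >= 5))
  expect_equal(nrow(site_filters(co, 5)), sum(co$site_id %in% keep))
})

test_that("leave-one-site-out is stable on separable clusters and beats a random control", {
  rs <- test_regions()
  cc <- cohort_config(n_hc = 20, n_mdd = 240, n_sites = 5, seed = 13)
  sim <- simulate_deviation_maps(240, rs, cc)
  prim <- cluster_subjects(sim$Z, 2, n_restarts = 10, seed = 14)
  rep <- leave_one_site_out(sim$Z, sim$site, k = 2, seed = 14, primary = prim,
                            n_restarts = 10)
  expect_equal(rep$n_failed, 0)
  expect_true(all(rep$per_site$overlap > 95))
  expect_gte(rep$min_overlap, min(rep$per_site$overlap))
  # random-relabeling control: far below the observed fold overlaps
  set.seed(15)
  ctrl <- align_labels(prim$labels,
                       stats::setNames(sample(1:2, 240, TRUE), names(prim$labels)))
  expect_true(all(rep$per_site$overlap > ctrl$overlap))
  expect_error(leave_one_site_out(sim$Z, rep("s1", 240), k = 2), ">= 3 sites")
})

test_that("subgroup reclustering reproduces primary labels when structure is subgroup-independent", {
  rs <- test_regions()
  cc <- cohort_config(n_hc = 20, n_mdd = 260, n_sites = 4, seed = 16)
  mdd <- generate_mdd_cohort(cc, rs)
  sim <- simulate_deviation_maps(260, rs, cc)
  rownames(sim$Z) <- mdd$cohort$subject_id
  prim <- cluster_subjects(sim$Z, 2, n_restarts = 10, seed = 17)
  rep <- subgroup_validation(sim$Z, mdd$cohort, prim,
                             groupings = c("male", "female", "medicated"),
                             seed = 17, n_restarts = 10)
  expect_true(all(rep$per_subgroup$overlap >= 90))
  expect_true(all(rep$per_subgroup$ari > 0.6))
  # undersized subgroup is skipped with a warning
  tiny <- mdd$cohort
  tiny$episode_status <- "medicated"
  tiny$episode_status[1] <- "FEDN"
  expect_warning(
    subgroup_validation(sim$Z, tiny, prim, groupings = c("FEDN", "male"),
                        seed = 18, n_restarts = 5),
    "too small")
})

test_that("structureless maps give near-zero subgroup ARI", {
  set.seed(19)
  Z <- matrix(stats::rnorm(80 * 30), 80)
  rownames(Z) <- sprintf("s%03d", 1:80)
  prim <- cluster_subjects(Z, 2, n_restarts = 10, seed = 20)
  sub <- sample(80, 20)
  res <- cluster_subjects(Z[sub, ], 2, n_restarts = 10, seed = 21)
  al <- align_labels(prim$labels, res$labels)
  ari <- adjusted_rand(prim$labels[names(al$labels)], al$labels)
  expect_lt(abs(ari), 0.4)
})

test_that("end-to-end subtype recovery under the default planted structure", {
  rs <- test_regions()
  cc <- cohort_config(n_hc = 20, n_mdd = 600, n_sites = 6, seed = 22)
  sim <- simulate_deviation_maps(600, rs, cc)
  prim <- cluster_subjects(sim$Z, 2, n_restarts = 20, seed = 23)
  expect_gt(adjusted_rand(prim$labels, sim$subtype), 0.8)
  minority <- min(table(prim$labels)) / 600
  planted <- mean(sim$subtype == 1)
  expect_lt(abs(minority - planted), 0.03)
})
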