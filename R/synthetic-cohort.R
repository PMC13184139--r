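# Synthetic multi-site cohort generator.
#
# Emulates the statistical structure a ReHo normative-modeling study assumes:
# nonlinear age trajectories with sex offsets in healthy controls, additive and
# multiplicative site effects following the ComBat generative model, and two
# patient subtypes with opposing network-level deviation patterns of planted
# effect size. Every downstream stage of the package is testable on its output.

#' Canonical network labels
#'
#' Seven cortical networks plus subcortex used to group the 246 atlas regions.
#'
#' @return Character vector of the 8 network codes.
#' @export
network_labels <- function() {
  c("FPCN", "VAN", "DMN", "LN", "DAN", "SMN", "VN", "SUB")
}

#' Generate region specifications for a 246-region parcellation
#'
#' Assigns each of the 246 regions to one of the 8 canonical networks (at
#' least 10 regions per network) and gives it a lifespan trajectory of the
#' form \eqn{f(age) = a + b (age - 40) + c (age - 40)^2} plus a sex-specific
#' intercept offset. Roughly half the regions increase with age and half
#' decrease, mirroring the two trajectory patterns seen in normative ReHo
#' models.
#'
#' @param n_networks Number of networks; must be 8 (kept as an argument for
#'   interface symmetry).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A `data.frame` of class `region_specs` with one row per region:
#'   `region_id`, `network`, `trajectory_kind`, `intercept`,
#'   `slope_per_decade` (ReHo units per 10 years), `curvature`
#'   (ReHo units per year^2), `sex_offset` (added for females).
#' @export
generate_region_specs <- function(n_networks = 8, seed = 1) {
  if (n_networks != 8) {
    stop("n_networks must be 8 (seven cortical networks plus subcortex)")
  }
  set.seed(seed)
  n_regions <- 246L
  nets <- network_labels()
  # at least 10 regions per network; distribute the remainder at random
  sizes <- rep(10L, 8)
  extra <- tabulate(sample.int(8, n_regions - sum(sizes), replace = TRUE), 8)
  sizes <- sizes + extra
  network <- sample(rep(nets, times = sizes))

  kind <- sample(rep(c("increasing", "decreasing"), each = n_regions / 2))
  slope_dec <- stats::runif(n_regions, 0.005, 0.030) *
    ifelse(kind == "increasing", 1, -1)
  b <- slope_dec / 10
  # curvature bounded so the quadratic stays monotone over ages 0..80
  curv <- stats::runif(n_regions, 0, 1) * b / (2 * 80) *
    sample(c(-1, 1), n_regions, replace = TRUE)
  specs <- data.frame(
    region_id = seq_len(n_regions),
    network = network,
    trajectory_kind = kind,
    intercept = stats::runif(n_regions, 0.35, 0.65),
    slope_per_decade = slope_dec,
    curvature = curv,
    sex_offset = stats::rnorm(n_regions, 0, 0.01),
    stringsAsFactors = FALSE
  )
  class(specs) <- c("region_specs", "data.frame")
  specs
}

#' Evaluate a region's normative trajectory
#'
#' @param specs A `region_specs` data frame (or a subset of its rows).
#' @param age Numeric vector of ages in years.
#' @param sex Character/factor vector, `"M"` or `"F"`, recycled against `age`.
#' @return Matrix `length(age)` x `nrow(specs)` of noiseless trajectory values.
#' @export
trajectory_values <- function(specs, age, sex) {
  sex <- rep_len(as.character(sex), length(age))
  a <- age - 40
  female <- as.numeric(sex == "F")
  vapply(seq_len(nrow(specs)), function(r) {
    specs$intercept[r] + (specs$slope_per_decade[r] / 10) * a +
      specs$curvature[r] * a^2 + specs$sex_offset[r] * female
  }, numeric(length(age)))
}

#' Default planted network effects
#'
#' Between-subtype Cohen's d of the Z-deviation shift per network
#' (subtype 1 minus subtype 2). Transmodal networks (FPCN, VAN, DMN, LN)
#' carry negative values: subtype 1 is shifted down there and subtype 2 up;
#' unimodal networks (DAN, SMN, VN) the reverse. Magnitudes span the
#' 0.40-1.81 range reported for network-level subtype differences.
#'
#' @return Named numeric vector over the 8 networks.
#' @export
default_network_effects <- function() {
  c(FPCN = -1.75, VAN = -1.20, DMN = -0.90, LN = -0.40,
    DAN = 1.00, SMN = 1.81, VN = 0.52, SUB = 0.00)
}

#' Default planted clinical effects
#'
#' Subtype-1-minus-subtype-2 standardized differences for the clinical
#' variables, the planted medication-rate association (Cramer's V scale),
#' and the within-subtype-1 duration-severity correlation.
#'
#' @return Named list of effect settings.
#' @export
default_clinical_effects <- function() {
  list(
    age_d = -0.19,            # subtype 1 younger
    hamd_d = 0.17,            # subtype 1 more severe
    anxiety_somatization_d = -0.15,  # subtype 2 higher
    insight_d = -0.25,        # subtype 1 lower item-17 score (better insight)
    medication_rates = c(0.55, 0.642),  # per subtype; Cramer's V ~ 0.09
    duration_severity_r = -0.21        # within subtype 1 only
  )
}

#' Build and validate a cohort configuration
#'
#' Defaults mirror the study scale (1011 HC, 1101 MDD, 22 sites) and the
#' reported subtype structure (36/64 split, network effects of absolute d
#' 0.40-1.81). Tests and examples run at reduced n.
#'
#' @param n_hc,n_mdd Numbers of healthy controls and patients.
#' @param n_sites Number of acquisition sites.
#' @param site_sizes Optional integer vector summing to `n_hc + n_mdd`;
#'   autogenerated (near-equal) when `NULL`.
#' @param age_range Two ages in years.
#' @param sex_ratio Proportion of females.
#' @param site_location_sd SD of additive site offsets (ReHo units), drawn per
#'   site x region.
#' @param site_scale_range Range of multiplicative site noise scales, drawn
#'   per site x region.
#' @param noise_sd Residual SD in ReHo units before site scaling.
#' @param subtype_proportions Two positive proportions summing to 1.
#' @param network_effects Named vector over networks: between-subtype Cohen's
#'   d of the planted Z shift; see [default_network_effects()].
#' @param clinical_effects List as produced by [default_clinical_effects()].
#' @param seed Integer root seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 1011, n_mdd = 1101, n_sites = 22,
                          site_sizes = NULL,
                          age_range = c(18, 65), sex_ratio = 0.6,
                          site_location_sd = 0.05,
                          site_scale_range = c(0.8, 1.25),
                          noise_sd = 0.08,
                          subtype_proportions = c(0.36, 0.64),
                          network_effects = default_network_effects(),
                          clinical_effects = default_clinical_effects(),
                          seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid cohort_config: field '%s' %s", field, msg))
  }
  chk(is.numeric(n_hc) && n_hc >= 1, "n_hc", "must be a positive count")
  chk(is.numeric(n_mdd) && n_mdd >= 1, "n_mdd", "must be a positive count")
  chk(is.numeric(n_sites) && n_sites >= 1, "n_sites", "must be a positive count")
  chk(length(age_range) == 2 && diff(age_range) > 0, "age_range",
      "must be an increasing pair of ages")
  chk(sex_ratio > 0 && sex_ratio < 1, "sex_ratio", "must lie in (0, 1)")
  chk(site_location_sd >= 0, "site_location_sd", "must be non-negative")
  chk(length(site_scale_range) == 2 && all(site_scale_range > 0) &&
        site_scale_range[1] <= site_scale_range[2], "site_scale_range",
      "must be a positive non-decreasing pair")
  chk(noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(length(subtype_proportions) == 2 && all(subtype_proportions > 0) &&
        all(subtype_proportions < 1) &&
        abs(sum(subtype_proportions) - 1) < 1e-8, "subtype_proportions",
      "must be two proportions in (0,1) summing to 1")
  chk(all(is.finite(network_effects)) &&
        all(network_labels() %in% names(network_effects)), "network_effects",
      "must be finite and named over all 8 networks")
  n_total <- n_hc + n_mdd
  if (is.null(site_sizes)) {
    site_sizes <- rep(n_total %/% n_sites, n_sites)
    if (n_total %% n_sites > 0) {
      site_sizes[seq_len(n_total %% n_sites)] <- site_sizes[seq_len(n_total %% n_sites)] + 1L
    }
  }
  chk(length(site_sizes) == n_sites && sum(site_sizes) == n_total,
      "site_sizes", "must have one entry per site and sum to n_hc + n_mdd")
  cfg <- list(
    n_hc = as.integer(n_hc), n_mdd = as.integer(n_mdd),
    n_sites = as.integer(n_sites), site_sizes = as.integer(site_sizes),
    age_range = age_range, sex_ratio = sex_ratio,
    site_location_sd = site_location_sd, site_scale_range = site_scale_range,
    noise_sd = noise_sd, subtype_proportions = subtype_proportions,
    network_effects = network_effects[network_labels()],
    clinical_effects = clinical_effects,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Site effect parameters are a deterministic function of (seed, n_sites,
# regions) so the HC and MDD generators share the same site structure.
.site_params <- function(config, n_regions) {
  set.seed(config$seed + 104729L)
  list(
    location = matrix(stats::rnorm(config$n_sites * n_regions,
                                   0, config$site_location_sd),
                      nrow = config$n_sites),
    scale = matrix(stats::runif(config$n_sites * n_regions,
                                config$site_scale_range[1],
                                config$site_scale_range[2]),
                   nrow = config$n_sites)
  )
}

# Allocate subjects to sites proportionally to the configured site sizes.
.assign_sites <- function(config, n, offset) {
  set.seed(config$seed + offset)
  probs <- config$site_sizes / sum(config$site_sizes)
  sample.int(config$n_sites, n, replace = TRUE, prob = probs)
}

.draw_demographics <- function(config, n) {
  list(
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  )
}

# noiseless trajectory + site location + site-scaled noise
.reho_matrix <- function(config, regions, age, sex, site, extra_shift = NULL) {
  n <- length(age)
  f <- trajectory_values(regions, age, sex)
  sp <- .site_params(config, nrow(regions))
  y <- f + sp$location[site, , drop = FALSE]
  if (!is.null(extra_shift)) y <- y + extra_shift
  if (config$noise_sd > 0) {
    eps <- matrix(stats::rnorm(n * nrow(regions), 0, config$noise_sd), nrow = n)
    y <- y + eps * sp$scale[site, , drop = FALSE]
  }
  colnames(y) <- sprintf("region_%03d", regions$region_id)
  y
}

#' Generate a healthy-control cohort
#'
#' Each region r of subject i is drawn as
#' \eqn{f_r(age_i, sex_i) + \gamma_{s(i),r} + \delta_{s(i),r}\,\epsilon},
#' \eqn{\epsilon \sim N(0, noise\_sd)}: the ComBat generative model around
#' the region's normative trajectory.
#'
#' @param config A [cohort_config()].
#' @param regions A `region_specs` data frame.
#' @return List with `cohort` (data frame of subject records) and `features`
#'   (n x 246 ReHo matrix, rownames = subject ids).
#' @export
generate_hc_cohort <- function(config, regions) {
  stopifnot(inherits(config, "cohort_config"), inherits(regions, "region_specs"))
  n <- config$n_hc
  site <- .assign_sites(config, n, offset = 7L)
  dem <- .draw_demographics(config, n)
  y <- .reho_matrix(config, regions, dem$age, dem$sex, site)
  ids <- sprintf("HC%04d", seq_len(n))
  rownames(y) <- ids
  cohort <- data.frame(
    subject_id = ids, age = dem$age, sex = dem$sex,
    site_id = sprintf("site%02d", site), group = "HC",
    true_subtype = NA_integer_,
    hamd17_total = NA_real_, anxiety_somatization = NA_real_,
    insight_item = NA_real_, illness_duration = NA_real_,
    medicated = NA, episode_status = NA_character_,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, features = y)
}

# per-region Z-shift (in planted Z units) for a subtype under the configured
# network effect pattern; subtype 1 gets +d/2 of the signed network effect,
# subtype 2 gets -d/2.
.subtype_shift_z <- function(config, regions, subtype) {
  d <- config$network_effects[regions$network]
  if (subtype == 1L) d / 2 else -d / 2
}

# truncated-normal draw by clipping; adequate for planted clinical scores
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.draw_clinical <- function(config, subtype) {
  eff <- config$clinical_effects
  n <- length(subtype)
  s1 <- subtype == 1L
  sd_age <- 11; sd_hamd <- 5; sd_anx <- 3; sd_ins <- 0.6
  age <- stats::rnorm(n, 35 + ifelse(s1, 1, -1) * eff$age_d * sd_age / 2, sd_age)
  age <- .clip(age, config$age_range[1], config$age_range[2])
  duration <- .clip(stats::rnorm(n, 5, 5), 0.1, 40)
  zdur <- as.numeric(scale(duration))
  rho <- eff$duration_severity_r
  hamd_noise <- stats::rnorm(n)
  hamd_core <- ifelse(s1, rho * zdur + sqrt(1 - rho^2) * hamd_noise, hamd_noise)
  hamd <- .clip(21 + ifelse(s1, 1, -1) * eff$hamd_d * sd_hamd / 2 +
                  sd_hamd * hamd_core, 0, 52)
  anx <- .clip(stats::rnorm(n, 7 + ifelse(s1, 1, -1) *
                              eff$anxiety_somatization_d * sd_anx / 2, sd_anx), 0, 18)
  insight <- round(.clip(stats::rnorm(n, 0.8 + ifelse(s1, 1, -1) *
                                        eff$insight_d * sd_ins / 2, sd_ins), 0, 2))
  med_p <- eff$medication_rates[subtype]
  medicated <- stats::runif(n) < med_p
  first_episode <- stats::runif(n) < 0.6
  status <- ifelse(medicated, "medicated",
                   ifelse(first_episode, "FEDN", "recurrent"))
  data.frame(
    age = age, hamd17_total = hamd, anxiety_somatization = anx,
    insight_item = insight, illness_duration = duration,
    medicated = medicated, episode_status = status,
    stringsAsFactors = FALSE
  )
}

#' Generate a patient cohort with two planted subtypes
#'
#' Patients are assigned subtype 1 with probability
#' `subtype_proportions[1]`. Regional ReHo follows the same generative model
#' as [generate_hc_cohort()] plus a subtype shift: subtype 1 is shifted by
#' d/2 of the signed network effect (in planted Z units, scaled to ReHo
#' units by `noise_sd`), subtype 2 by the opposite amount, producing the
#' opposing network-level deviation patterns. Clinical variables carry the
#' configured subtype effects, including a negative duration-severity
#' correlation in subtype 1 only.
#'
#' @inheritParams generate_hc_cohort
#' @param hc_reference Optional fitted [fit_normative_set()] result; unused by
#'   the generator itself (deviations are computed downstream) but accepted so
#'   callers can thread a reference through.
#' @return List with `cohort` and `features` as in [generate_hc_cohort()].
#' @export
generate_mdd_cohort <- function(config, regions, hc_reference = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(regions, "region_specs"))
  n <- config$n_mdd
  site <- .assign_sites(config, n, offset = 13L)
  set.seed(config$seed + 17L)
  subtype <- ifelse(stats::runif(n) < config$subtype_proportions[1], 1L, 2L)
  clin <- .draw_clinical(config, subtype)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  shift_z <- t(vapply(subtype, function(s) .subtype_shift_z(config, regions, s),
                      numeric(nrow(regions))))
  y <- .reho_matrix(config, regions, clin$age, sex, site,
                    extra_shift = shift_z * config$noise_sd)
  ids <- sprintf("MDD%04d", seq_len(n))
  rownames(y) <- ids
  cohort <- data.frame(
    subject_id = ids, age = clin$age, sex = sex,
    site_id = sprintf("site%02d", site), group = "MDD",
    true_subtype = subtype,
    clin[, c("hamd17_total", "anxiety_somatization", "insight_item",
             "illness_duration", "medicated", "episode_status")],
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, features = y)
}

#' Simulate patient deviation maps with planted subtype structure
#'
#' Draws subjects x 246 Z-deviation maps directly: standard-normal noise plus
#' the planted subtype network shift (d/2 with opposite signs per subtype).
#' This is the natural input scale for the subtyping stage and is what the
#' clustering validation exercises operate on.
#'
#' @param n Number of patients.
#' @param regions A `region_specs` data frame.
#' @param config A [cohort_config()]; supplies proportions, network effects,
#'   site sizes and the seed.
#' @return List with `Z` (n x 246 matrix), `subtype` (planted labels) and
#'   `site` (site ids).
#' @export
simulate_deviation_maps <- function(n, regions, config) {
  stopifnot(inherits(config, "cohort_config"), inherits(regions, "region_specs"))
  site <- .assign_sites(config, n, offset = 23L)
  set.seed(config$seed + 29L)
  subtype <- ifelse(stats::runif(n) < config$subtype_proportions[1], 1L, 2L)
  shift <- t(vapply(subtype, function(s) .subtype_shift_z(config, regions, s),
                    numeric(nrow(regions))))
  Z <- shift + matrix(stats::rnorm(n * nrow(regions)), nrow = n)
  colnames(Z) <- sprintf("region_%03d", regions$region_id)
  rownames(Z) <- sprintf("MDD%04d", seq_len(n))
  list(Z = Z, subtype = subtype, site = sprintf("site%02d", site))
}

#' Generate a synthetic 4D time-series image with a 246-parcel atlas
#'
#' Tiles the grid with disjoint cubic parcels (3x3x3 voxels) labeled 1..246.
#' Each parcel's voxels share a latent signal:
#' \eqn{x = \sqrt{s}\, latent + \sqrt{1-s}\, noise} with synchrony
#' \eqn{s \in [0,1]}, so within-parcel concordance is monotone in `s`.
#'
#' @param shape Integer 3-vector of spatial extents.
#' @param n_timepoints Number of time points (>= 10).
#' @param regions A `region_specs` data frame (supplies region ids).
#' @param synchrony Within-parcel synchrony in `[0, 1]`.
#' @param noise_sd SD of the independent voxel noise component.
#' @param seed Integer seed.
#' @return List with `data` (4D array), `mask` (3D logical: labeled voxels),
#'   `atlas` (3D integer array, 0 background) and `region_table`.
#' @export
generate_voxel_dataset <- function(shape = c(21, 21, 18), n_timepoints = 30,
                                   regions, synchrony = 0.9, noise_sd = 1,
                                   seed = 1) {
  stopifnot(length(shape) == 3, n_timepoints >= 10)
  m <- 3L  # parcel edge length
  blocks <- floor(shape / m)
  if (prod(blocks) < nrow(regions)) {
    stop(sprintf("grid %s too small to host %d disjoint %d-voxel parcels",
                 paste(shape, collapse = "x"), nrow(regions), m^3))
  }
  set.seed(seed)
  atlas <- array(0L, dim = shape)
  idx <- 0L
  coords <- expand.grid(bx = seq_len(blocks[1]), by = seq_len(blocks[2]),
                        bz = seq_len(blocks[3]))
  for (r in seq_len(nrow(regions))) {
    idx <- idx + 1L
    b <- coords[idx, ]
    xs <- ((b$bx - 1L) * m + 1L):(b$bx * m)
    ys <- ((b$by - 1L) * m + 1L):(b$by * m)
    zs <- ((b$bz - 1L) * m + 1L):(b$bz * m)
    atlas[xs, ys, zs] <- regions$region_id[r]
  }
  dat <- array(0, dim = c(shape, n_timepoints))
  for (r in seq_len(nrow(regions))) {
    vox <- which(atlas == regions$region_id[r])
    latent <- stats::rnorm(n_timepoints)
    for (t in seq_len(n_timepoints)) {
      slice <- sqrt(synchrony) * latent[t] +
        sqrt(max(0, 1 - synchrony)) * noise_sd * stats::rnorm(length(vox))
      page <- dat[, , , t]
      page[vox] <- slice
      dat[, , , t] <- page
    }
  }
  list(
    data = dat,
    mask = atlas > 0L,
    atlas = atlas,
    region_table = regions[, c("region_id", "network")]
  )
}

#' Write / read cohort tables and feature matrices as TSV
#'
#' @param x Cohort data frame or feature matrix.
#' @param path Output path.
#' @return `path`, invisibly (writers); data frame or matrix (readers).
#' @export
write_cohort_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
write_features_tsv <- function(x, path) {
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_cohort_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
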