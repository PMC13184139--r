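# End-to-end orchestration: generate (or load) -> [reho] -> harmonize ->
# fit normative models -> deviations -> deviation statistics -> subtype ->
# validate, from a single configuration, with seeds, checksums and per-stage
# timings captured in a run manifest.

#' Build a pipeline configuration
#'
#' @param cohort A [cohort_config()] for synthetic mode, or `NULL` when
#'   loading real tables via `feature_path` / `phenotype_path`.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param feature_path,phenotype_path Real-data mode inputs (TSV); see
#'   [load_feature_table()].
#' @param harmonize Run ComBat across sites.
#' @param harmonize_diagnosis Include diagnosis as a preserved covariate in
#'   harmonization (off by default; sites are harmonized on HC + patients
#'   jointly with age and sex preserved).
#' @param run_cv Run 10-fold cross-validation of the normative models.
#' @param k Number of subtypes; `NULL` selects k by majority vote.
#' @param k_range Candidate k values when selecting.
#' @param threshold Extreme-deviation threshold.
#' @param k_folds CV folds.
#' @param n_restarts k-means restarts.
#' @param gpr_restarts GPR optimizer restarts.
#' @param min_site_n Minimum site size kept before clustering validation.
#' @param run_loso Run leave-one-site-out validation.
#' @param run_subgroups Run subgroup validation.
#' @param seed Root seed; every stage derives its own stream from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), out_dir = tempfile("run"),
                            feature_path = NULL, phenotype_path = NULL,
                            harmonize = TRUE, harmonize_diagnosis = FALSE,
                            run_cv = FALSE, k = NULL, k_range = 2:8,
                            threshold = 2.6, k_folds = 10, n_restarts = 50,
                            gpr_restarts = 2, min_site_n = 10,
                            run_loso = TRUE, run_subgroups = FALSE,
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments; the
#' `cohort:` block maps onto [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort) else cohort_config()
  y$cohort <- NULL
  do.call(pipeline_config, c(list(cohort = cohort), y))
}

#' Load and validate a regional feature table with its phenotype table
#'
#' The feature TSV must have a `subject_id` key column plus 246 numeric
#' region columns; the phenotype TSV must carry `subject_id`, `age`, `sex`,
#' `site_id`, `group`. Tables are joined on `subject_id`; rows with missing
#' demographics are dropped with a message.
#'
#' @param feature_path Feature TSV path.
#' @param phenotype_path Phenotype TSV path.
#' @return List with `features` (matrix) and `cohort` (data frame).
#' @export
load_feature_table <- function(feature_path, phenotype_path) {
  feats <- utils::read.delim(feature_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (names(feats)[1] != "subject_id") stop("feature table must start with a subject_id column")
  if (ncol(feats) - 1 != 246) {
    stop(sprintf("feature table must have 246 region columns, found %d",
                 ncol(feats) - 1))
  }
  if (anyDuplicated(feats$subject_id)) stop("duplicated subject_id in feature table")
  m <- as.matrix(feats[, -1])
  if (!is.numeric(m)) stop("non-numeric cells in feature table")
  rownames(m) <- feats$subject_id
  pheno <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "site_id", "group")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must contain: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(pheno$subject_id)) stop("duplicated subject_id in phenotype table")
  complete <- !is.na(pheno$age) & !is.na(pheno$sex) & !is.na(pheno$site_id)
  if (any(!complete)) {
    message(sprintf("load_feature_table: dropped %d subject(s) with missing demographics",
                    sum(!complete)))
    pheno <- pheno[complete, , drop = FALSE]
  }
  shared <- intersect(pheno$subject_id, rownames(m))
  if (length(shared) == 0) stop("no subjects shared between the two tables")
  list(features = m[shared, , drop = FALSE],
       cohort = pheno[match(shared, pheno$subject_id), , drop = FALSE])
}

.stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: cohort generation (or loading),
#' ComBat harmonization across sites, per-region GPR normative models fitted
#' on the HC subjects, patient Z-deviation maps, deviation summaries and
#' region-wise group statistics, k-means subtyping (with optional
#' majority-vote k selection), and stability validation. Stage outputs are
#' written as TSV/JSON under `config$out_dir` together with a run manifest
#' (config snapshot, package version, seeds, per-stage wall-clock and output
#' checksums).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with all stage objects and the
#'   manifest; also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rehonorm")),
    seed = config$seed,
    stages = list()
  )
  log_stage <- function(name, seconds, files = character(0)) {
    manifest$stages[[name]] <<- list(
      seconds = round(seconds, 3),
      outputs = as.list(tools::md5sum(files))
    )
  }
  out <- function(f) file.path(config$out_dir, f)

  # -- cohort ----------------------------------------------------------------
  st <- .stage_time({
    regions <- generate_region_specs(seed = config$seed)
    if (!is.null(config$feature_path)) {
      loaded <- load_feature_table(config$feature_path, config$phenotype_path)
      cohort <- loaded$cohort
      features <- loaded$features
    } else {
      cc <- config$cohort
      cc$seed <- config$seed
      hc <- generate_hc_cohort(cc, regions)
      mdd <- generate_mdd_cohort(cc, regions)
      cohort <- rbind(hc$cohort, mdd$cohort)
      features <- rbind(hc$features, mdd$features)
    }
    list(regions = regions, cohort = cohort, features = features)
  })
  regions <- st$value$regions
  cohort <- st$value$cohort
  features <- st$value$features
  write_cohort_tsv(cohort, out("cohort.tsv"))
  write_features_tsv(features, out("features_raw.tsv"))
  log_stage("cohort", st$seconds, c(out("cohort.tsv"), out("features_raw.tsv")))

  # -- harmonization ---------------------------------------------------------
  if (config$harmonize && length(unique(cohort$site_id)) > 1) {
    st <- .stage_time({
      covs <- data.frame(age = cohort$age,
                         sex = as.numeric(cohort$sex == "F"))
      if (config$harmonize_diagnosis) {
        covs$diagnosis <- as.numeric(cohort$group == "MDD")
      }
      combat_harmonize(features, cohort$site_id, covs)
    })
    features_h <- st$value
    write_combat_model(attr(features_h, "model"), out("combat_model.json"))
    write_features_tsv(features_h, out("features_harmonized.tsv"))
    log_stage("harmonize", st$seconds,
              c(out("combat_model.json"), out("features_harmonized.tsv")))
  } else {
    if (config$harmonize) message("run_pipeline: single site, harmonization skipped")
    features_h <- features
    log_stage("harmonize", 0)
  }

  # -- normative models on HC ------------------------------------------------
  is_hc <- cohort$group == "HC"
  covariates <- data.frame(age = cohort$age, sex = cohort$sex)
  st <- .stage_time({
    fit_normative_set(features_h[is_hc, , drop = FALSE],
                      covariates[is_hc, , drop = FALSE],
                      n_restarts = config$gpr_restarts, seed = config$seed)
  })
  model_set <- st$value
  log_stage("fit_normative", st$seconds)

  cv <- NULL
  if (config$run_cv) {
    st <- .stage_time({
      crossval_metrics(features_h[is_hc, , drop = FALSE],
                       covariates[is_hc, , drop = FALSE],
                       k_folds = config$k_folds, seed = config$seed,
                       n_restarts = config$gpr_restarts)
    })
    cv <- st$value
    utils::write.table(
      data.frame(region = model_set$feature_names, smse = cv$smse, msll = cv$msll),
      out("cv_metrics.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("crossval", st$seconds, out("cv_metrics.tsv"))
  }

  # -- patient deviations ----------------------------------------------------
  is_pt <- !is_hc
  st <- .stage_time({
    deviation_map(model_set, features_h[is_pt, , drop = FALSE],
                  covariates[is_pt, , drop = FALSE],
                  threshold = config$threshold)
  })
  Z <- st$value
  write_features_tsv(Z, out("deviations.tsv"))
  log_stage("deviations", st$seconds, out("deviations.tsv"))

  # -- deviation statistics --------------------------------------------------
  st <- .stage_time({
    list(indices = deviation_indices(Z, config$threshold),
         overlap = overlap_map(Z, config$threshold),
         prevalence = prevalence_stats(Z, config$threshold))
  })
  devstats <- st$value
  utils::write.table(devstats$indices, out("deviation_indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(devstats$overlap, out("overlap_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(devstats$prevalence, out("prevalence.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("devstats", st$seconds,
            c(out("deviation_indices.tsv"), out("overlap_map.tsv"),
              out("prevalence.json")))

  # -- subtyping -------------------------------------------------------------
  pt_cohort <- cohort[is_pt, , drop = FALSE]
  st <- .stage_time({
    ksel <- NULL
    k <- config$k
    if (is.null(k)) {
      ksel <- select_k(Z, k_range = config$k_range, seed = config$seed)
      k <- ksel$k
    }
    primary <- cluster_subjects(Z, k, n_restarts = config$n_restarts,
                                seed = config$seed)
    list(ksel = ksel, primary = primary,
         network_Z = network_aggregate(Z, regions))
  })
  subtype <- st$value
  utils::write.table(
    data.frame(subject_id = rownames(Z), subtype = subtype$primary$labels),
    out("subtype_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("subtype", st$seconds, out("subtype_labels.tsv"))

  # -- validation ------------------------------------------------------------
  validation <- list()
  if (config$run_loso) {
    st <- .stage_time({
      kept <- site_filters(pt_cohort, config$min_site_n)
      keep_idx <- match(kept$subject_id, rownames(Z))
      leave_one_site_out(Z[keep_idx, , drop = FALSE], kept$site_id,
                         k = subtype$primary$k, seed = config$seed,
                         n_restarts = config$n_restarts)
    })
    validation$loso <- st$value
    utils::write.table(st$value$per_site, out("loso.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("validate_loso", st$seconds, out("loso.tsv"))
  }
  if (config$run_subgroups) {
    st <- .stage_time({
      subgroup_validation(Z, pt_cohort, subtype$primary, seed = config$seed,
                          n_restarts = config$n_restarts)
    })
    validation$subgroups <- st$value
    utils::write.table(st$value$per_subgroup, out("subgroups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("validate_subgroups", st$seconds, out("subgroups.tsv"))
  }

  manifest$config <- .config_snapshot(config)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  structure(list(
    regions = regions, cohort = cohort, features = features,
    features_harmonized = features_h, model_set = model_set, cv = cv,
    Z = Z, devstats = devstats, subtype = subtype, validation = validation,
    manifest = manifest, out_dir = config$out_dir
  ), class = "pipeline_result")
}

.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$cohort <- if (!is.null(snap$cohort)) unclass(snap$cohort) else NULL
  snap
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", nrow(x$cohort), "subjects,",
      ncol(x$features), "regions\n")
  cat("  subtypes: k =", x$subtype$primary$k, "| sizes:",
      paste(table(x$subtype$primary$labels), collapse = "/"), "\n")
  if (!is.null(x$validation$loso)) {
    cat(sprintf("  leave-one-site-out min overlap: %.2f%%\n",
                x$validation$loso$min_overlap))
  }
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
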