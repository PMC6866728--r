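# Pipeline orchestration: synthesise-or-load, then VBM, covariance, age and
# clinical stages from a single config, with a machine-readable JSON report.

#' Pipeline configuration
#'
#' One object driving the full analysis.  All randomness flows from
#' `master_seed`, expanded into fixed per-stage seeds.  The configuration
#' round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input `"synthetic"` (generate a cohort from `synth`) or
#'   `"manifest"` (load volumes listed in `manifest_path` with
#'   `mask_path`, and clinical visits from `clinical_path`).
#' @param stages character subset of
#'   `c("vbm", "covariance", "age", "clinical")`.
#' @param synth a [synth_config()] (synthetic mode).
#' @param manifest_path,mask_path,clinical_path input files (manifest mode).
#' @param covariates GLM covariates for the group comparison.
#' @param cluster_forming_t,n_perm,connectivity,alpha permutation cluster-FWE
#'   settings.
#' @param covariance_p_cutoff display threshold for within-group covariance
#'   maps.
#' @param n_repeats balanced-subsampling repeats for the larger group.
#' @param interaction_correction `"fdr"` or `"cluster_fwe"` for the
#'   covariance group-difference map.
#' @param slope_cutoff,min_cluster slope-difference map settings
#'   (GM-units/year, voxels).
#' @param fdr_q FDR level for age interaction and covariance FDR branches.
#' @param clinical_scores score names to associate with the seed ROI;
#'   defaults to all scores present.
#' @param clinical_group `"pd"` (default), `"control"` or `"all"`.
#' @param out_dir output directory for maps and tables.
#' @param master_seed integer master RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "manifest"),
                            stages = c("vbm", "covariance", "age", "clinical"),
                            synth = synth_config(),
                            manifest_path = NULL, mask_path = NULL,
                            clinical_path = NULL,
                            covariates = c("age", "sex"),
                            cluster_forming_t = 4, n_perm = 5000,
                            connectivity = 26, alpha = 0.05,
                            covariance_p_cutoff = 6e-8, n_repeats = 100,
                            interaction_correction = c("fdr", "cluster_fwe"),
                            slope_cutoff = 0.002, min_cluster = 20,
                            fdr_q = 0.05,
                            clinical_scores = NULL,
                            clinical_group = c("pd", "control", "all"),
                            out_dir = tempfile("vbm_pipeline_"),
                            master_seed = 1L) {
  input <- match.arg(input)
  interaction_correction <- match.arg(interaction_correction)
  clinical_group <- match.arg(clinical_group)
  bad <- setdiff(stages, c("vbm", "covariance", "age", "clinical"))
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  if (input == "manifest" && (is.null(manifest_path) || is.null(mask_path)))
    stopf("manifest mode needs manifest_path and mask_path")
  structure(list(input = input, stages = stages, synth = synth,
                 manifest_path = manifest_path, mask_path = mask_path,
                 clinical_path = clinical_path, covariates = covariates,
                 cluster_forming_t = cluster_forming_t,
                 n_perm = as.integer(n_perm),
                 connectivity = as.integer(connectivity), alpha = alpha,
                 covariance_p_cutoff = covariance_p_cutoff,
                 n_repeats = as.integer(n_repeats),
                 interaction_correction = interaction_correction,
                 slope_cutoff = slope_cutoff,
                 min_cluster = as.integer(min_cluster),
                 fdr_q = fdr_q, clinical_scores = clinical_scores,
                 clinical_group = clinical_group,
                 out_dir = out_dir, master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path YAML output path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  x$synth$regions <- as.data.frame(x$synth$regions)
  x$synth$clinical <- as.data.frame(x$synth$clinical)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sy <- x$synth
  synth <- synth_config(
    dim = unlist(sy$dim), voxel_mm = sy$voxel_mm,
    n_control = sy$n_control, n_pd = sy$n_pd,
    age_range = unlist(sy$age_range), prop_male = sy$prop_male,
    baseline = sy$baseline, brain_radius = sy$brain_radius,
    noise_sd = sy$noise_sd, smooth_sigma_mm = sy$smooth_sigma_mm,
    regions = dplyr::bind_rows(sy$regions),
    atrophy_frac = sy$atrophy_frac,
    slope_control = sy$slope_control, slope_pd = sy$slope_pd,
    age_ref = sy$age_ref,
    loading_control = sy$loading_control, loading_pd = sy$loading_pd,
    latent_scale = sy$latent_scale,
    clinical = dplyr::bind_rows(sy$clinical),
    clinical_noise_sd = sy$clinical_noise_sd,
    missing_rate = sy$missing_rate, seed = sy$seed)
  pipeline_config(
    input = x$input, stages = unlist(x$stages), synth = synth,
    manifest_path = x$manifest_path, mask_path = x$mask_path,
    clinical_path = x$clinical_path, covariates = unlist(x$covariates),
    cluster_forming_t = x$cluster_forming_t, n_perm = x$n_perm,
    connectivity = x$connectivity, alpha = x$alpha,
    covariance_p_cutoff = x$covariance_p_cutoff, n_repeats = x$n_repeats,
    interaction_correction = x$interaction_correction,
    slope_cutoff = x$slope_cutoff, min_cluster = x$min_cluster,
    fdr_q = x$fdr_q, clinical_scores = unlist(x$clinical_scores),
    clinical_group = x$clinical_group,
    out_dir = x$out_dir, master_seed = x$master_seed)
}

clusters_for_report <- function(clusters) {
  as.data.frame(dplyr::select(clusters, -dplyr::any_of("voxels")))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate-or-load, VBM group
#' comparison, structural covariance, age trajectories, clinical
#' association), writes maps and tables into `config$out_dir`, and returns a
#' report aggregating every stage's tables with a provenance log (stage
#' seeds, parameters and problem sizes).  The report is also written as
#' `report.json`; with a fixed master seed the report is byte-identical
#' across runs.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a nested list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$master_seed, 5)
  report <- list(provenance = list(
    master_seed = config$master_seed,
    stage_seeds = list(simulate = seeds[1], vbm = seeds[2],
                       covariance = seeds[3], age = seeds[4],
                       clinical = seeds[5]),
    stages = as.list(config$stages), input = config$input))

  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- input ---------------------------------------------------------------
  atlas <- NULL; truth <- NULL; clinical_tbl <- NULL
  if (config$input == "synthetic") {
    syn <- run_stage("simulate", function() {
      cfg <- config$synth
      cfg$seed <- seeds[1]
      generate_cohort(cfg)
    })
    cohort <- syn$cohort
    clinical_tbl <- syn$clinical
    truth <- syn$truth
    atlas <- synthetic_atlas(syn)
    report$simulate <- list(
      n_control = truth$config$n_control, n_pd = truth$config$n_pd,
      grid = truth$config$dim, smooth_sigma_mm = truth$config$smooth_sigma_mm,
      planted = list(atrophy_frac = truth$config$atrophy_frac,
                     slope_control = truth$config$slope_control,
                     slope_pd = truth$config$slope_pd,
                     loading_control = truth$config$loading_control,
                     loading_pd = truth$config$loading_pd))
  } else {
    cohort <- run_stage("load", function() {
      mask <- read_mask(config$mask_path)
      load_cohort(utils::read.csv(config$manifest_path, stringsAsFactors = FALSE),
                  mask)
    })
    if (!is.null(config$clinical_path))
      clinical_tbl <- utils::read.csv(config$clinical_path,
                                      stringsAsFactors = FALSE)
    report$load <- list(n = nrow(cohort$values),
                        n_voxels = ncol(cohort$values))
  }
  g <- cohort$subjects$group

  seed_roi <- if (!is.null(truth)) {
    brain_mask(truth$seed_mask, truth$affine)
  } else NULL
  age_roi <- if (!is.null(truth)) {
    brain_mask(truth$age_mask, truth$affine)
  } else NULL

  # --- vbm -----------------------------------------------------------------
  if ("vbm" %in% config$stages) {
    res <- run_stage("vbm", function() {
      design <- build_design_matrix(cohort$subjects, config$covariates)
      fwe <- permutation_cluster_fwe(
        cohort, design, cluster_forming_t = config$cluster_forming_t,
        n_perm = config$n_perm, connectivity = config$connectivity,
        alpha = config$alpha, atlas = atlas, seed = seeds[2])
      unc <- uncorrected_tmap(cohort, covariates = config$covariates,
                              connectivity = config$connectivity,
                              atlas = atlas)
      save_stat_map(fwe$tmap, file.path(config$out_dir, "vbm_tmap.nii.gz"))
      write_cluster_table(fwe$clusters,
                          file.path(config$out_dir, "vbm_clusters.csv"))
      list(fwe = fwe, unc = unc)
    })
    report$vbm <- list(
      n_perm = res$fwe$n_perm, exhaustive = res$fwe$exhaustive,
      cluster_forming_t = config$cluster_forming_t,
      clusters = clusters_for_report(res$fwe$clusters),
      n_significant = sum(res$fwe$clusters$significant),
      uncorrected = list(threshold = res$unc$threshold,
                         clusters = clusters_for_report(res$unc$clusters)))
  }

  # --- covariance ----------------------------------------------------------
  if ("covariance" %in% config$stages) {
    if (is.null(seed_roi)) stopf("covariance stage needs a seed ROI (synthetic mode provides one)")
    res <- run_stage("covariance", function() {
      seed_vals <- extract_roi_mean(cohort, seed_roi)
      i_con <- which(g == "control"); i_pd <- which(g == "pd")
      sub_con <- gm_cohort(cohort$values[i_con, , drop = FALSE], cohort$mask,
                           cohort$subjects[i_con, ])
      cm_con <- seed_covariance_map(sub_con, seed_vals[i_con],
                                    p_cutoff = config$covariance_p_cutoff)
      n_target <- min(length(i_con), length(i_pd))
      subsets <- balanced_subsample(i_pd, n_target,
                                    n_repeats = config$n_repeats,
                                    seed = seeds[3])
      cm_pd <- average_covariance_map(cohort, seed_vals, subsets)
      imap <- interaction_difference_map(
        cohort, seed_vals, correction = config$interaction_correction,
        cluster_forming_t = config$cluster_forming_t,
        n_perm = min(config$n_perm, 1000),
        connectivity = config$connectivity, alpha = config$alpha,
        q = config$fdr_q, atlas = atlas, seed = seeds[3])
      save_stat_map(cm_con$r_map, file.path(config$out_dir, "cov_r_control.nii.gz"))
      save_stat_map(cm_pd$r_map, file.path(config$out_dir, "cov_r_pd_mean.nii.gz"))
      save_stat_map(imap$tmap, file.path(config$out_dir, "cov_t_d.nii.gz"))
      list(cm_con = cm_con, cm_pd = cm_pd, imap = imap,
           seed_vals = seed_vals, n_target = n_target)
    })
    report$covariance <- list(
      n_control = sum(g == "control"), n_target = res$n_target,
      n_repeats = config$n_repeats,
      n_sig_control = sum(res$cm_con$significant),
      correction = config$interaction_correction,
      max_abs_t_d = max(abs(res$imap$fit$t_d[!res$imap$fit$flagged])),
      clusters = if (!is.null(res$imap$clusters))
        clusters_for_report(res$imap$clusters) else NULL,
      n_fdr_significant = if (!is.null(res$imap$significant))
        sum(res$imap$significant, na.rm = TRUE) else NULL)
  }

  # --- age -----------------------------------------------------------------
  if ("age" %in% config$stages) {
    res <- run_stage("age", function() {
      i_con <- which(g == "control"); i_pd <- which(g == "pd")
      sub <- function(i) gm_cohort(cohort$values[i, , drop = FALSE],
                                   cohort$mask, cohort$subjects[i, ])
      m_con <- age_slope_map(sub(i_con))
      m_pd <- age_slope_map(sub(i_pd))
      sd_map <- slope_difference_map(m_pd, m_con, cutoff = config$slope_cutoff,
                                     min_cluster = config$min_cluster,
                                     connectivity = config$connectivity,
                                     atlas = atlas)
      ai <- age_interaction_test(cohort, small_volume = age_roi,
                                 q = config$fdr_q)
      rois <- if (!is.null(age_roi)) list(age_region = age_roi) else list()
      roi_tbl <- if (length(rois)) roi_slope_comparison(cohort, rois) else NULL
      save_stat_map(m_con, file.path(config$out_dir, "age_slope_control.nii.gz"))
      save_stat_map(m_pd, file.path(config$out_dir, "age_slope_pd.nii.gz"))
      save_stat_map(sd_map$diff_map, file.path(config$out_dir, "age_slope_diff.nii.gz"))
      list(m_con = m_con, m_pd = m_pd, sd_map = sd_map, ai = ai,
           roi_tbl = roi_tbl)
    })
    report$age <- list(
      cutoff = config$slope_cutoff, min_cluster = config$min_cluster,
      clusters = clusters_for_report(res$sd_map$clusters),
      n_fdr_significant = sum(res$ai$significant),
      roi_slopes = if (!is.null(res$roi_tbl)) as.data.frame(res$roi_tbl) else NULL)
  }

  # --- clinical ------------------------------------------------------------
  if ("clinical" %in% config$stages && !is.null(clinical_tbl)) {
    if (is.null(seed_roi)) stopf("clinical stage needs a seed ROI")
    res <- run_stage("clinical", function() {
      keep <- switch(config$clinical_group,
                     pd = which(g == "pd"),
                     control = which(g == "control"),
                     all = seq_along(g))
      sub <- gm_cohort(cohort$values[keep, , drop = FALSE], cohort$mask,
                       cohort$subjects[keep, ])
      roi_means <- extract_roi_mean(sub, seed_roi)
      matches <- match_nearest_visit(clinical_tbl,
                                     sub$subjects[, c("subject_id", "scan_date")])
      scores <- config$clinical_scores %||% sort(unique(matches$score))
      assoc <- purrr::map(scores, function(sc) {
        m <- matches[matches$score == sc, ]
        out <- tryCatch(suppressMessages(correlate_roi_score(roi_means, m)),
                        error = function(e) tibble::tibble(
                          r = NA_real_, p = NA_real_, n = 0L, n_dropped = NA_integer_))
        adj <- tryCatch({
          val <- m$value[match(sub$subjects$subject_id, m$subject_id)]
          adjusted_association(roi_means, val, sub$subjects$age,
                               sub$subjects$sex)
        }, error = function(e) tibble::tibble(coefficient = NA_real_,
                                              t = NA_real_, p = NA_real_,
                                              n = 0L))
        tibble::tibble(score = sc, r = out$r, p = out$p, n = out$n,
                       adjusted_t = adj$t, adjusted_p = adj$p)
      }) |> dplyr::bind_rows()
      utils::write.csv(assoc, file.path(config$out_dir, "clinical_association.csv"),
                       row.names = FALSE)
      assoc
    })
    report$clinical <- list(group = config$clinical_group,
                            associations = as.data.frame(res))
  }

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", Date = "ISO8601")
  invisible(report)
}
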