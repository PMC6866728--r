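# Cross-sectional age-related grey-matter change: per-group voxel-wise age
# slopes in natural units, thresholded slope-difference maps, the
# interaction test for slope differences, and ROI-level slope comparison.

#' Voxel-wise age slope map for one group
#'
#' Per-voxel OLS slope of grey matter on age in natural units
#' (GM-density per year): the cross-sectional estimate of the predicted rate
#' of grey-matter change.
#'
#' @param cohort a [gm_cohort()] restricted to one group.
#' @param ages subject ages in years; defaults to the cohort's `age` column.
#' @return a [stat_map()] of slopes (statistic `"slope"`).
#' @export
age_slope_map <- function(cohort, ages = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"))
  ages <- ages %||% cohort$subjects$age
  n <- nrow(cohort$values)
  if (length(ages) != n) stopf("ages must match subject count")
  if (n < 3) stopf("need at least 3 subjects")
  if (stats::sd(ages) == 0) stopf("zero age variance")
  ac <- ages - mean(ages)
  sxx <- sum(ac^2)
  slopes <- drop(crossprod(sweep(cohort$values, 2, colMeans(cohort$values)), ac)) / sxx
  stat_map(slopes, cohort$mask, statistic = "slope",
           contrast = "GM-density change per year")
}

#' Thresholded age-slope difference map
#'
#' The reported difference is control slope minus pd slope, so a positive
#' value means extra age-related decline in the pd group.  Voxels whose
#' absolute difference reaches the cutoff are kept (sign preserved), then
#' connected components smaller than `min_cluster` voxels are removed.
#' Defaults match the conventional operating point: 0.002 GM-units/year,
#' 20-voxel minimum cluster, 26-neighbour connectivity.
#'
#' @param pd_map,control_map slope [stat_map()]s on the same grid.
#' @param cutoff absolute slope-difference cutoff (GM-units/year).
#' @param min_cluster minimum surviving cluster size in voxels.
#' @param connectivity 6, 18 or 26.
#' @param atlas optional atlas for peak labels.
#' @return list of class `slope_difference`: the thresholded signed
#'   difference [stat_map()] (`NA` where below cutoff or filtered) and the
#'   cluster tibble with `direction` (`"pd_faster"`/`"pd_slower"`).
#' @export
slope_difference_map <- function(pd_map, control_map, cutoff = 0.002,
                                 min_cluster = 20, connectivity = 26,
                                 atlas = NULL) {
  stopifnot(inherits(pd_map, "stat_map"), inherits(control_map, "stat_map"))
  if (!identical(pd_map$mask$dim, control_map$mask$dim) ||
      max(abs(pd_map$mask$affine - control_map$mask$affine)) > 1e-6)
    stopf("slope maps are on different grids")
  diffv <- map_values(control_map) - map_values(pd_map)
  mask <- pd_map$mask
  abs_map <- stat_map(abs(diffv), mask, "abs slope difference")
  # strict threshold on >= cutoff: pass cutoff minus a relative epsilon
  clusters <- label_clusters(abs_map, cutoff * (1 - 1e-12), connectivity, atlas)
  clusters <- clusters[clusters$size >= min_cluster, , drop = FALSE]
  keep <- sort(unlist(clusters$voxels))
  out_arr <- array(NA_real_, mask$dim)
  sign_arr <- array(NA_real_, mask$dim)
  sign_arr[mask$data] <- diffv
  out_arr[keep] <- sign_arr[keep]
  diff_map <- stat_map(out_arr, mask, "slope difference (control - pd)")
  if (nrow(clusters) > 0) {
    clusters$cluster_id <- seq_len(nrow(clusters))
    clusters$peak_stat <- purrr::map_dbl(clusters$voxels, function(v) {
      dv <- sign_arr[v]; dv[which.max(abs(dv))]
    })
    clusters$direction <- ifelse(clusters$peak_stat > 0, "pd_faster", "pd_slower")
  } else {
    clusters$direction <- character(0)
  }
  structure(list(diff_map = diff_map, clusters = clusters, cutoff = cutoff,
                 min_cluster = min_cluster, connectivity = connectivity),
            class = "slope_difference")
}

#' @export
print.slope_difference <- function(x, ...) {
  cat(sprintf(
    "<slope_difference> |diff| >= %g/yr, clusters >= %d voxels (%d-connectivity)\n",
    x$cutoff, x$min_cluster, x$connectivity))
  print(dplyr::select(x$clusters, -dplyr::any_of("voxels")), n = 10)
  invisible(x)
}

#' Voxel-wise interaction test for age-slope differences
#'
#' Fits the interaction model with X = age and Y = local grey matter, both
#' z-scored within group, and corrects the two-sided `t_d` p-values by
#' BH-FDR — within a small-volume mask when one is supplied, otherwise over
#' the whole analysis mask.
#'
#' @param cohort a [gm_cohort()] with both groups.
#' @param ages subject ages; defaults to the cohort `age` column.
#' @param small_volume optional ROI [brain_mask()] restricting the correction.
#' @param q FDR level.
#' @return object of class `age_interaction`: `t_d` [stat_map()], the fit,
#'   the FDR table over tested voxels, and the tested voxel columns.
#' @export
age_interaction_test <- function(cohort, ages = NULL, small_volume = NULL,
                                 q = 0.05) {
  stopifnot(inherits(cohort, "gm_cohort"))
  ages <- ages %||% cohort$subjects$age
  g <- cohort$subjects$group
  fit <- fit_interaction(cohort$values, ages, g)
  tmap <- stat_map(fit$t_d, cohort$mask, "t_d", df = fit$df,
                   contrast = "group x age interaction on local GM")
  cols <- seq_along(fit$t_d)
  if (!is.null(small_volume)) {
    stopifnot(inherits(small_volume, "brain_mask"))
    cols <- which(!is.na(match(cohort$voxel_idx, which(small_volume$data))))
    if (length(cols) == 0) stopf("small-volume mask does not intersect the cohort mask")
  }
  p <- fit$p_d[cols]
  p[fit$flagged[cols]] <- NA_real_
  fd <- suppressWarnings(fdr_correct(p, q))
  sig <- rep(FALSE, length(fit$t_d))
  sig[cols] <- !is.na(fd$significant) & fd$significant
  structure(list(tmap = tmap, fit = fit, fdr = fd, tested_cols = cols,
                 significant = sig, q = q),
            class = "age_interaction")
}

#' @export
print.age_interaction <- function(x, ...) {
  cat(sprintf("<age_interaction> %d voxels tested, %d FDR-significant at q = %g\n",
              length(x$tested_cols), sum(x$significant), x$q))
  print(x$tmap)
  invisible(x)
}

#' ROI-level age-slope comparison between groups
#'
#' For each ROI: mean grey matter per subject, per-group natural-unit age
#' slope, and the interaction-model `t_d`/`p_d` on the ROI means.
#'
#' @param cohort a [gm_cohort()] with both groups.
#' @param rois named list of ROI [brain_mask()]s (lateralised masks should be
#'   supplied as separate entries).
#' @param ages subject ages; defaults to the cohort `age` column.
#' @return tibble: `region`, `slope_control`, `slope_pd`,
#'   `slope_difference` (control - pd), `t_d`, `p_d`, `n_voxels`.
#' @export
roi_slope_comparison <- function(cohort, rois, ages = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"), length(rois) >= 1)
  ages <- ages %||% cohort$subjects$age
  g <- cohort$subjects$group
  if (is.null(names(rois)) || any(names(rois) == ""))
    stopf("rois must be a named list")
  purrr::map(names(rois), function(nm) {
    m <- extract_roi_mean(cohort, rois[[nm]])
    slope_of <- function(rows) {
      ac <- ages[rows] - mean(ages[rows])
      sum(ac * (m[rows] - mean(m[rows]))) / sum(ac^2)
    }
    fit <- fit_interaction(m, ages, g)
    tibble::tibble(region = nm,
                   slope_control = slope_of(which(g == "control")),
                   slope_pd = slope_of(which(g == "pd")),
                   t_d = fit$t_d, p_d = fit$p_d,
                   n_voxels = sum(rois[[nm]]$data))
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(slope_difference = .data$slope_control - .data$slope_pd,
                  .after = "slope_pd")
}
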