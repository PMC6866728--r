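# Seed-based structural covariance maps per group and the group-by-covariate
# interaction test for covariance differences, with balanced subsampling.

# Per-group z-scoring of a subjects x voxels matrix (or vector).  Columns
# with zero within-group variance are set to 0 and flagged.
zscore_by_group <- function(M, g) {
  M <- as.matrix(M)
  flagged <- rep(FALSE, ncol(M))
  for (lev in unique(g)) {
    rows <- which(g == lev)
    Mg <- M[rows, , drop = FALSE]
    mu <- colMeans(Mg)
    Mc <- sweep(Mg, 2, mu)
    sdv <- sqrt(colSums(Mc^2) / (length(rows) - 1))
    zero <- sdv <= .Machine$double.eps * pmax(1, abs(mu))
    flagged <- flagged | zero
    sdv[zero] <- 1
    M[rows, ] <- sweep(Mc, 2, sdv, `/`)
  }
  list(M = M, flagged = flagged)
}

#' Fit the group-interaction regression model per voxel
#'
#' Least-squares fit of `Y = a + b*X + c*PD + d*PD*X + e` with PD coded
#' 0 = control, 1 = pd.  The dependent and independent variables are
#' z-scored within each group first (the model's normalisation step), which
#' makes `b` read as the control-group correlation and `d` as the
#' correlation difference; `t_d = d / se(d)` with `df = n - 4` tests for a
#' group difference in the X-Y coupling.  Because the group dummy saturates
#' per-group intercept and slope, the fit is computed in closed form as two
#' per-group simple regressions with a pooled residual variance — identical
#' to the full four-column least-squares solution.
#'
#' `y` and `x` may each be a single series (length n) or a subjects x voxels
#' matrix; a single series is recycled across voxels.
#'
#' @param y dependent variable (seed GM in covariance mode, local GM in age
#'   mode).
#' @param x independent variable (local GM in covariance mode, age in age
#'   mode).
#' @param group `"control"`/`"pd"` vector of length n.
#' @param normalise z-score within group first (the default; turning it off
#'   fits the raw-scale model).
#' @return object of class `interaction_fit`: per-voxel `a`, `b`, `c`, `d`,
#'   `t_d`, `p_d`, `df`, `sigma2`, and `flagged` (zero within-group variance
#'   in x or y).
#' @export
fit_interaction <- function(y, x, group, normalise = TRUE) {
  g <- as.character(group)
  if (!all(g %in% c("control", "pd"))) stopf("group must be 'control'/'pd'")
  n <- length(g)
  Y <- as.matrix(y); X <- as.matrix(x)
  V <- max(ncol(Y), ncol(X))
  if (ncol(Y) == 1 && V > 1) Y <- Y[, rep(1, V), drop = FALSE]
  if (ncol(X) == 1 && V > 1) X <- X[, rep(1, V), drop = FALSE]
  if (nrow(Y) != n || nrow(X) != n) stopf("y/x rows must match group length")
  n0 <- sum(g == "control"); n1 <- sum(g == "pd")
  if (n0 < 3 || n1 < 3) stopf("need at least 3 subjects per group")
  df <- n - 4
  flagged <- rep(FALSE, V)
  if (normalise) {
    zy <- zscore_by_group(Y, g); zx <- zscore_by_group(X, g)
    Y <- zy$M; X <- zx$M
    flagged <- zy$flagged | zx$flagged
  }
  stats_for <- function(rows) {
    Yg <- Y[rows, , drop = FALSE]; Xg <- X[rows, , drop = FALSE]
    mx <- colMeans(Xg); my <- colMeans(Yg)
    Xc <- sweep(Xg, 2, mx); Yc <- sweep(Yg, 2, my)
    sxx <- colSums(Xc^2); sxy <- colSums(Xc * Yc); syy <- colSums(Yc^2)
    zero <- sxx == 0
    b <- ifelse(zero, 0, sxy / ifelse(zero, 1, sxx))
    rss <- syy - b * sxy
    list(b = b, a = my - b * mx, sxx = sxx, rss = rss, zero = zero)
  }
  s0 <- stats_for(which(g == "control"))
  s1 <- stats_for(which(g == "pd"))
  flagged <- flagged | s0$zero | s1$zero
  d <- s1$b - s0$b
  sigma2 <- (s0$rss + s1$rss) / df
  se_d <- sqrt(sigma2 * (1 / s0$sxx + 1 / s1$sxx))
  t_d <- d / se_d
  t_d[flagged] <- 0
  p_d <- 2 * stats::pt(-abs(t_d), df)
  structure(list(a = s0$a, b = s0$b, c = s1$a - s0$a, d = d,
                 t_d = t_d, p_d = p_d, se_d = se_d, sigma2 = sigma2,
                 df = df, n = n, flagged = flagged,
                 normalised = normalise),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  V <- length(x$d)
  if (V == 1) {
    cat(sprintf(
      "<interaction_fit> n = %d, df = %d\n  b = %.4f, d = %.4f, t_d = %.3f, p_d = %.3g\n",
      x$n, x$df, x$b, x$d, x$t_d, x$p_d))
  } else {
    cat(sprintf("<interaction_fit> %d voxels, n = %d, df = %d, max |t_d| = %.3f\n",
                V, x$n, x$df, max(abs(x$t_d))))
  }
  invisible(x)
}

#' Seed-based structural covariance map for one group
#'
#' Pearson correlation between the per-subject seed value and local grey
#' matter at every in-mask voxel, with two-sided p-values, thresholded at a
#' fixed display cutoff (default the conventional very strict 6e-8) or by
#' BH-FDR.
#'
#' @param cohort a [gm_cohort()] restricted to one group (or any subject set).
#' @param seed_values per-subject seed means, e.g. from [extract_roi_mean()].
#' @param p_cutoff display threshold on p (used when `method = "fixed"`).
#' @param method `"fixed"` p cutoff or `"fdr"` (BH at `q`).
#' @param q FDR level when `method = "fdr"`.
#' @return object of class `covariance_map`: `r` and `p` [stat_map()]s, the
#'   significance mask, `n`, and the threshold description.  Zero-variance
#'   voxels get r = 0 and are flagged.
#' @export
seed_covariance_map <- function(cohort, seed_values, p_cutoff = 6e-8,
                                method = c("fixed", "fdr"), q = 0.05) {
  stopifnot(inherits(cohort, "gm_cohort"))
  method <- match.arg(method)
  n <- nrow(cohort$values)
  if (n < 3) stopf("need at least 3 subjects")
  if (length(seed_values) != n) stopf("seed values must match subject count")
  s <- seed_values - mean(seed_values)
  ss <- sqrt(sum(s^2))
  if (ss == 0) stopf("seed values have zero variance")
  Y <- cohort$values
  Yc <- sweep(Y, 2, colMeans(Y))
  denom <- sqrt(colSums(Yc^2))
  flagged <- denom == 0
  r <- ifelse(flagged, 0, drop(crossprod(Yc, s)) / (ifelse(flagged, 1, denom) * ss))
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  p[flagged] <- 1
  sig <- if (method == "fixed") p < p_cutoff else fdr_correct(p, q)$significant
  structure(list(
    r_map = stat_map(r, cohort$mask, "r", df = df, contrast = "seed covariance"),
    p_map = stat_map(p, cohort$mask, "p", df = df),
    significant = sig, flagged = flagged, n = n,
    threshold = if (method == "fixed") sprintf("p < %g", p_cutoff)
                else sprintf("BH-FDR q = %g", q)),
    class = "covariance_map")
}

#' @export
print.covariance_map <- function(x, ...) {
  cat(sprintf("<covariance_map> n = %d, %d voxels significant at %s\n",
              x$n, sum(x$significant), x$threshold))
  print(x$r_map)
  invisible(x)
}

#' Balanced random subsamples of a subject set
#'
#' Uniform sampling without replacement, used to match the larger group's
#' size to the smaller one before computing covariance maps.
#'
#' @param indices integer vector of candidate subject row indices.
#' @param n_target subsample size (must not exceed `length(indices)`).
#' @param n_repeats number of subsamples.
#' @param seed RNG seed.
#' @return list of integer index vectors, one per repeat.  When
#'   `n_target == length(indices)` every repeat is the identity selection.
#' @export
balanced_subsample <- function(indices, n_target, n_repeats = 100, seed = NULL) {
  indices <- as.integer(indices)
  if (n_target > length(indices))
    stopf("n_target (%d) exceeds group size (%d)", n_target, length(indices))
  if (!is.null(seed)) set.seed(seed)
  if (n_target == length(indices))
    return(replicate(n_repeats, indices, simplify = FALSE))
  replicate(n_repeats, sort(sample(indices, n_target)), simplify = FALSE)
}

#' Average covariance map over balanced subsamples
#'
#' Recomputes the seed covariance map on each subsample and returns the
#' per-voxel mean correlation.
#'
#' @param cohort a [gm_cohort()].
#' @param seed_values per-subject seed means for the full cohort.
#' @param subsets list of subject index vectors, e.g. from
#'   [balanced_subsample()].
#' @return object of class `covariance_map` holding the averaged r map (no p
#'   thresholding; `significant` is all-FALSE).
#' @export
average_covariance_map <- function(cohort, seed_values, subsets) {
  stopifnot(inherits(cohort, "gm_cohort"), length(subsets) >= 1)
  acc <- NULL
  for (idx in subsets) {
    sub <- gm_cohort(cohort$values[idx, , drop = FALSE], cohort$mask,
                     cohort$subjects[idx, ])
    cm <- seed_covariance_map(sub, seed_values[idx])
    rv <- map_values(cm$r_map)
    acc <- if (is.null(acc)) rv else acc + rv
  }
  r_mean <- acc / length(subsets)
  structure(list(
    r_map = stat_map(r_mean, cohort$mask, "r",
                     contrast = sprintf("mean seed covariance over %d subsamples",
                                        length(subsets))),
    p_map = NULL, significant = rep(FALSE, length(r_mean)),
    flagged = rep(FALSE, length(r_mean)),
    n = length(subsets[[1]]),
    threshold = "none (averaged map)"),
    class = "covariance_map")
}

#' Group-difference map of seed covariance (interaction test)
#'
#' Fits the interaction model at every voxel with Y = seed grey matter and
#' X = local grey matter (both z-scored within group) and maps
#' `t_d`, the statistic on the group-by-X term.  Multiplicity is handled
#' either by permutation cluster-extent FWE (group labels shuffled) or by
#' BH-FDR on the voxel p-values.  Flagged zero-variance voxels are excluded
#' from the correction.
#'
#' @param cohort a [gm_cohort()] containing both groups.
#' @param seed_values per-subject seed means.
#' @param correction `"cluster_fwe"` or `"fdr"`.
#' @param cluster_forming_t,n_perm,connectivity,alpha,seed settings for the
#'   permutation FWE branch (two-sided cluster forming on |t_d|).
#' @param q FDR level for the FDR branch.
#' @param atlas optional atlas for peak labels.
#' @return object of class `interaction_map`: the `t_d` [stat_map()], the
#'   voxel-wise fit, and either a corrected cluster tibble or the FDR
#'   significance vector.
#' @export
interaction_difference_map <- function(cohort, seed_values,
                                       correction = c("cluster_fwe", "fdr"),
                                       cluster_forming_t = 4, n_perm = 1000,
                                       connectivity = 26, alpha = 0.05,
                                       q = 0.05, atlas = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"))
  correction <- match.arg(correction)
  g <- cohort$subjects$group
  fit <- fit_interaction(seed_values, cohort$values, g)
  tmap <- stat_map(fit$t_d, cohort$mask, "t_d", df = fit$df,
                   contrast = "group x local-GM interaction on seed GM")
  out <- list(tmap = tmap, fit = fit, correction = correction)
  if (correction == "cluster_fwe") {
    dimv <- cohort$mask$dim
    voxel_idx <- cohort$voxel_idx
    max_cluster <- function(tv) {
      supra <- which(abs(tv) > cluster_forming_t & !fit$flagged)
      if (length(supra) == 0) return(0L)
      max(tabulate(connected_components(voxel_idx[supra], dimv, connectivity)))
    }
    abs_map <- stat_map(ifelse(fit$flagged, 0, abs(fit$t_d)), cohort$mask,
                        "abs t_d", df = fit$df)
    clusters <- label_clusters(abs_map, cluster_forming_t, connectivity, atlas)
    if (!is.null(seed)) set.seed(seed)
    null_max <- integer(n_perm)
    for (b in seq_len(n_perm))
      null_max[b] <- max_cluster(fit_interaction(seed_values, cohort$values,
                                                 sample(g))$t_d)
    if (nrow(clusters) > 0) {
      clusters$peak_stat <- purrr::map_dbl(clusters$voxels, function(v) {
        tv <- tmap$data[v]; tv[which.max(abs(tv))]
      })
      clusters$p_corrected <- vapply(clusters$size, function(s)
        (1 + sum(null_max >= s)) / (n_perm + 1), 0)
      clusters$significant <- clusters$p_corrected <= alpha
    }
    out$clusters <- clusters
    out$null_max_size <- null_max
    out$n_perm <- n_perm
  } else {
    p <- fit$p_d
    p[fit$flagged] <- NA_real_
    fd <- suppressWarnings(fdr_correct(p, q))
    out$fdr <- fd
    out$significant <- fd$significant
  }
  structure(out, class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> correction: %s\n", x$correction))
  print(x$tmap)
  if (!is.null(x$clusters)) print(dplyr::select(x$clusters, -dplyr::any_of("voxels")), n = 10)
  if (!is.null(x$significant) && is.null(x$clusters))
    cat(sprintf("  %d voxels FDR-significant\n", sum(x$significant, na.rm = TRUE)))
  invisible(x)
}
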