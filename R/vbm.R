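# Voxel-wise GLM group comparison with covariates, permutation-based
# cluster-extent FWE correction, uncorrected t-maps, BH-FDR and
# clinical-score subgrouping.

#' Build a design matrix for the voxel-wise GLM
#'
#' Intercept plus a 0/1 group column (control = 0, pd = 1) plus requested
#' covariates.  `sex` is recoded 0/1 (F = 0, M = 1); numeric covariates are
#' passed through.  The default contrast tests the group grey-matter deficit
#' (control minus pd), the direction the VBM comparison reports.
#'
#' @param subjects subject table with at least a `group` column.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("age", "sex")`).
#' @return object of class `vbm_design`: list with the model matrix `X`,
#'   `contrast` vector and column names.
#' @export
build_design_matrix <- function(subjects, covariates = c("age", "sex")) {
  subjects <- tibble::as_tibble(subjects)
  if (!"group" %in% names(subjects)) stopf("subject table needs a 'group' column")
  grp <- subjects$group
  if (!all(grp %in% c("control", "pd")))
    stopf("group must be coded 'control'/'pd'")
  X <- cbind(intercept = 1, group = as.numeric(grp == "pd"))
  for (cv in covariates) {
    if (!cv %in% names(subjects)) stopf("covariate '%s' not in subject table", cv)
    v <- subjects[[cv]]
    if (anyNA(v)) stopf("covariate '%s' has missing values", cv)
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- sort(unique(v))
      if (length(lev) > 2) stopf("covariate '%s' has more than two levels", cv)
      v <- as.numeric(v == lev[length(lev)])
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  contrast <- as.numeric(colnames(X) == "group")
  structure(list(X = X, contrast = contrast, columns = colnames(X)),
            class = "vbm_design")
}

#' @export
print.vbm_design <- function(x, ...) {
  cat(sprintf("<vbm_design> %d subjects x %d terms: %s\n",
              nrow(x$X), ncol(x$X), paste(x$columns, collapse = ", ")))
  invisible(x)
}

# Core vectorised OLS contrast t over a voxel matrix.  Returns t, df and a
# flag for zero-residual-variance voxels (t set to 0 there).
glm_contrast_t <- function(Y, X, contrast) {
  n <- nrow(X); k <- ncol(X)
  df <- n - k
  if (df <= 0) stopf("non-positive degrees of freedom (n = %d, rank = %d)", n, k)
  XtX <- crossprod(X)
  Xi <- chol2inv(chol(XtX))
  B <- Xi %*% crossprod(X, Y)
  R <- Y - X %*% B
  rss <- colSums(R^2)
  s2 <- rss / df
  cvar <- drop(t(contrast) %*% Xi %*% contrast)
  eff <- drop(crossprod(contrast, B))
  se <- sqrt(s2 * cvar)
  flagged <- s2 <= .Machine$double.eps * max(1, max(abs(Y)))^2
  tt <- ifelse(flagged, 0, eff / se)
  list(t = tt, effect = eff, df = df, flagged = flagged)
}

#' Voxel-wise GLM contrast t-map
#'
#' Ordinary least squares at every in-mask voxel with a shared design;
#' returns the t statistic of the design's contrast.  Voxels with zero
#' residual variance get t = 0 and are flagged.
#'
#' @param cohort a [gm_cohort()].
#' @param design a [vbm_design()]; rows must align with the cohort.
#' @param contrast optional replacement contrast vector.
#' @return object of class `vbm_fit`: the t [stat_map()], `df`, `design`, and
#'   the flagged-voxel indicator.
#' @export
fit_voxelwise_glm <- function(cohort, design, contrast = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(design, "vbm_design"))
  if (nrow(design$X) != nrow(cohort$values))
    stopf("design has %d rows but cohort has %d subjects",
          nrow(design$X), nrow(cohort$values))
  ctr <- contrast %||% design$contrast
  fit <- glm_contrast_t(cohort$values, design$X, ctr)
  map <- stat_map(fit$t, cohort$mask, statistic = "t", df = fit$df,
                  contrast = paste0("c = (", paste(ctr, collapse = ", "),
                                    ") on (", paste(design$columns, collapse = ", "), ")"))
  structure(list(tmap = map, df = fit$df, design = design, contrast = ctr,
                 flagged = fit$flagged, n = nrow(cohort$values)),
            class = "vbm_fit")
}

#' @export
print.vbm_fit <- function(x, ...) {
  cat(sprintf("<vbm_fit> n = %d, df = %d, %d zero-variance voxels flagged\n",
              x$n, x$df, sum(x$flagged)))
  print(x$tmap)
  invisible(x)
}

# Fast contrast t for the permutation loop: avoids forming the residual
# matrix by using rss = y'y - (X'y)'B with y'y precomputed once.
contrast_t_fast <- function(Y, yty, X, contrast, df) {
  XtX <- crossprod(X)
  Xi <- chol2inv(chol(XtX))
  XtY <- crossprod(X, Y)
  B <- Xi %*% XtY
  rss <- pmax(yty - colSums(XtY * B), 0)
  se <- sqrt((rss / df) * drop(t(contrast) %*% Xi %*% contrast))
  tt <- drop(crossprod(contrast, B)) / se
  tt[!is.finite(tt)] <- 0
  tt
}

# all choose(n, k) index sets; used for exhaustive enumeration of group
# relabelings
all_relabelings <- function(n, k) utils::combn(n, k, simplify = FALSE)

#' Permutation cluster-extent FWE-corrected group comparison
#'
#' Thresholds the group-contrast t-map at a predefined cluster-forming
#' cutoff and judges observed cluster sizes against the permutation null
#' distribution of the maximal suprathreshold cluster size, obtained by
#' shuffling group labels while holding covariate rows fixed.  When the
#' number of distinct relabelings does not exceed `n_perm`, the null is
#' enumerated exhaustively; otherwise `n_perm` random relabelings are drawn
#' and the corrected p uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param cohort a [gm_cohort()] with a two-level `group` column.
#' @param design a [vbm_design()] built from the same subjects.
#' @param cluster_forming_t predefined statistic cutoff (default 4).
#' @param n_perm number of permutations (default 5000).
#' @param connectivity cluster connectivity: 6, 18 or 26.
#' @param alpha cluster-level significance level.
#' @param tail `"greater"` tests the contrast direction (default: grey-matter
#'   deficit in pd, i.e. control minus pd); `"two_sided"` cluster-forms on
#'   |t|.
#' @param atlas optional atlas for peak labels.
#' @param seed RNG seed for the permutation draw.
#' @return object of class `perm_fwe`: observed cluster tibble with
#'   `p_corrected` and `significant`, the t-map, the null distribution of
#'   maximal cluster size, and the settings used.
#' @export
permutation_cluster_fwe <- function(cohort, design, cluster_forming_t = 4,
                                    n_perm = 5000, connectivity = 26,
                                    alpha = 0.05,
                                    tail = c("greater", "two_sided"),
                                    atlas = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(design, "vbm_design"))
  tail <- match.arg(tail)
  if (n_perm < 100) warnf("n_perm = %d gives very coarse corrected p", n_perm)
  grp_col <- which(design$columns == "group")
  g <- design$X[, grp_col]
  n1 <- sum(g == 1)
  if (n1 < 2 || sum(g == 0) < 2) stopf("need at least 2 subjects per group")
  # deficit contrast: control minus pd, so atrophy in pd gives positive t
  ctr <- -as.numeric(design$columns == "group")

  Y <- cohort$values
  dimv <- cohort$mask$dim
  voxel_idx <- cohort$voxel_idx

  stat_of <- function(tvals) if (tail == "two_sided") abs(tvals) else tvals
  max_cluster <- function(tvals) {
    supra <- which(stat_of(tvals) > cluster_forming_t)
    if (length(supra) == 0) return(0L)
    memb <- connected_components(voxel_idx[supra], dimv, connectivity)
    max(tabulate(memb))
  }

  obs <- glm_contrast_t(Y, design$X, ctr)
  tmap <- stat_map(obs$t, cohort$mask, statistic = "t", df = obs$df,
                   contrast = "group deficit (control - pd)")
  clusters <- label_clusters(
    stat_map(stat_of(obs$t), cohort$mask, statistic = "t", df = obs$df),
    cluster_forming_t, connectivity, atlas)

  n_total <- choose(nrow(Y), n1)
  exhaustive <- n_total <= n_perm
  yty <- colSums(Y^2)
  if (exhaustive) {
    sets <- all_relabelings(nrow(Y), n1)
    null_max <- purrr::map_int(sets, function(ones) {
      Xp <- design$X
      Xp[, grp_col] <- 0
      Xp[ones, grp_col] <- 1
      max_cluster(contrast_t_fast(Y, yty, Xp, ctr, obs$df))
    })
    n_eff <- length(null_max)
    p_of <- function(sz) vapply(sz, function(s) mean(null_max >= s), 0)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_max <- integer(n_perm)
    Xp <- design$X
    for (b in seq_len(n_perm)) {
      Xp[, grp_col] <- sample(g)
      null_max[b] <- max_cluster(contrast_t_fast(Y, yty, Xp, ctr, obs$df))
    }
    n_eff <- n_perm
    p_of <- function(sz) vapply(sz, function(s) (1 + sum(null_max >= s)) / (n_perm + 1), 0)
  }

  if (nrow(clusters) > 0) {
    clusters$p_corrected <- p_of(clusters$size)
    clusters$significant <- clusters$p_corrected <= alpha
  } else {
    clusters$p_corrected <- numeric(0)
    clusters$significant <- logical(0)
  }

  structure(list(clusters = clusters, tmap = tmap, null_max_size = null_max,
                 n_perm = n_eff, exhaustive = exhaustive,
                 cluster_forming_t = cluster_forming_t,
                 connectivity = connectivity, alpha = alpha, tail = tail,
                 df = obs$df),
            class = "perm_fwe")
}

#' @export
print.perm_fwe <- function(x, ...) {
  cat(sprintf(
    "<perm_fwe> cluster-forming t > %g, %s%d permutations, alpha = %g (%s)\n",
    x$cluster_forming_t, if (x$exhaustive) "exhaustive " else "", x$n_perm,
    x$alpha, x$tail))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(dplyr::select(x$clusters, -dplyr::any_of("voxels")), n = 10)
  }
  invisible(x)
}

#' Uncorrected two-sample t-map
#'
#' Equal-variance two-sample comparison (optionally with age/sex covariates)
#' thresholded at a fixed statistic and p cutoff; the stricter of the two is
#' applied.  Defaults mirror the common uncorrected validation operating
#' point (T > 2.8, P < 0.005, two-tailed).
#'
#' @param cohort a [gm_cohort()] with a `group` column.
#' @param t_threshold statistic cutoff on |t|.
#' @param p_threshold two-sided p cutoff.
#' @param covariates covariate names to adjust for (default none).
#' @param connectivity cluster connectivity.
#' @param atlas optional atlas for peak labels.
#' @return list of class `uncorrected_tmap`: the signed t-map (control minus
#'   pd direction), the threshold used, and the cluster tibble flagged
#'   `"uncorrected"`.
#' @export
uncorrected_tmap <- function(cohort, t_threshold = 2.8, p_threshold = 0.005,
                             covariates = character(0), connectivity = 26,
                             atlas = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"))
  grp <- cohort$subjects$group
  if (length(unique(grp)) != 2 || any(table(grp) == 0))
    stopf("uncorrected map needs two non-empty groups")
  design <- build_design_matrix(cohort$subjects, covariates)
  fit <- fit_voxelwise_glm(cohort, design,
                           contrast = -as.numeric(design$columns == "group"))
  thr <- max(t_threshold, stats::qt(1 - p_threshold / 2, fit$df))
  abs_map <- stat_map(abs(map_values(fit$tmap)), cohort$mask, "abs t", fit$df)
  clusters <- label_clusters(abs_map, thr, connectivity, atlas)
  if (nrow(clusters) > 0) {
    # restore the signed peak statistic
    clusters$peak_stat <- purrr::map_dbl(clusters$voxels, function(v) {
      tv <- fit$tmap$data[v]
      tv[which.max(abs(tv))]
    })
  }
  clusters$correction <- rep("uncorrected", nrow(clusters))
  structure(list(tmap = fit$tmap, clusters = clusters, threshold = thr,
                 t_threshold = t_threshold, p_threshold = p_threshold,
                 df = fit$df),
            class = "uncorrected_tmap")
}

#' @export
print.uncorrected_tmap <- function(x, ...) {
  cat(sprintf("<uncorrected_tmap> |t| > %.3f (t > %g and two-sided p < %g), df = %d\n",
              x$threshold, x$t_threshold, x$p_threshold, x$df))
  print(dplyr::select(x$clusters, -dplyr::any_of("voxels")), n = 10)
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure on a vector of p-values; NaN entries are excluded with a
#' warning and returned as NA.
#'
#' @param p p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return tibble with `p`, `p_adjusted`, `significant`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  bad <- is.na(p)
  if (any(bad)) warnf("%d NaN p-values excluded from FDR correction", sum(bad))
  if (any(p[!bad] < 0 | p[!bad] > 1)) stopf("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  adj[!bad] <- stats::p.adjust(p[!bad], method = "BH")
  tibble::tibble(p = p, p_adjusted = adj,
                 significant = !is.na(adj) & adj <= q)
}

#' Split subjects by motor severity score
#'
#' Partition at a fixed threshold: score below the threshold is `mild`,
#' at-or-above is `moderate` (the convention used for MDS-UPDRS III
#' median-split subgrouping at 21).  Subjects with a missing score are
#' excluded with a message.
#'
#' @param subjects subject table.
#' @param score column name holding the score (default `"updrs3"`).
#' @param threshold split point (default 21).
#' @return the subject table, missing-score rows removed, with a `severity`
#'   factor column; attribute `n_missing` records the exclusions.
#' @export
median_split <- function(subjects, score = "updrs3", threshold = 21) {
  subjects <- tibble::as_tibble(subjects)
  if (!score %in% names(subjects)) stopf("score column '%s' not found", score)
  v <- subjects[[score]]
  n_missing <- sum(is.na(v))
  if (n_missing > 0)
    rlang::inform(sprintf("%d subjects excluded for missing %s", n_missing, score))
  out <- subjects[!is.na(v), ]
  out$severity <- factor(ifelse(out[[score]] < threshold, "mild", "moderate"),
                         levels = c("mild", "moderate"))
  attr(out, "n_missing") <- n_missing
  attr(out, "threshold") <- threshold
  out
}
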