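# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for the
# package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

stat_map_tibble <- function(map, value_name = "value") {
  idx <- which(map$mask$data)
  mm <- voxel_to_mm(map$mask$affine, linear_to_ijk(idx, map$mask$dim) - 1)
  out <- tibble::tibble(voxel = idx, x = mm[, 1], y = mm[, 2], z = mm[, 3],
                        value = map$data[idx])
  names(out)[names(out) == "value"] <- value_name
  out
}

#' @exportS3Method generics::tidy
tidy.stat_map <- function(x, ...) stat_map_tibble(x, x$statistic)

#' Tidy a voxel-wise GLM fit
#'
#' @param x a `vbm_fit`.
#' @param threshold if given, keep only voxels with |t| above it.
#' @param ... unused.
#' @return tibble: `voxel`, `x`, `y`, `z` (mm), `t`, `flagged`.
#' @exportS3Method generics::tidy
tidy.vbm_fit <- function(x, threshold = NULL, ...) {
  out <- stat_map_tibble(x$tmap, "t")
  out$flagged <- x$flagged
  if (!is.null(threshold)) out <- out[abs(out$t) > threshold, ]
  out
}

#' @exportS3Method generics::glance
glance.vbm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, max_t = max(abs(map_values(x$tmap))),
                 n_voxels = length(x$flagged), n_flagged = sum(x$flagged))
}

#' @exportS3Method generics::tidy
tidy.perm_fwe <- function(x, ...) dplyr::select(x$clusters, -dplyr::any_of("voxels"))

#' @exportS3Method generics::glance
glance.perm_fwe <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, exhaustive = x$exhaustive,
                 cluster_forming_t = x$cluster_forming_t,
                 connectivity = x$connectivity, alpha = x$alpha,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 min_p_corrected = if (nrow(x$clusters)) min(x$clusters$p_corrected)
                                   else NA_real_)
}

#' Tidy an interaction-model fit
#'
#' For a single-series fit, one row per coefficient (`a`, `b`, `c`, `d`) with
#' the `t`/`p` of the interaction term on the `d` row; for a voxel-wise fit,
#' one row per voxel.
#' @param x an `interaction_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.interaction_fit <- function(x, ...) {
  if (length(x$d) == 1) {
    tibble::tibble(term = c("a", "b", "c", "d"),
                   estimate = c(x$a, x$b, x$c, x$d),
                   statistic = c(NA, NA, NA, x$t_d),
                   p.value = c(NA, NA, NA, x$p_d))
  } else {
    tibble::tibble(voxel = seq_along(x$d), b = x$b, d = x$d,
                   t_d = x$t_d, p_d = x$p_d, flagged = x$flagged)
  }
}

#' @exportS3Method generics::glance
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, normalised = x$normalised,
                 n_series = length(x$d), n_flagged = sum(x$flagged))
}

#' @exportS3Method generics::tidy
tidy.covariance_map <- function(x, ...) {
  out <- stat_map_tibble(x$r_map, "r")
  if (!is.null(x$p_map)) out$p <- map_values(x$p_map)
  out$significant <- x$significant
  out
}

#' @exportS3Method generics::glance
glance.covariance_map <- function(x, ...) {
  tibble::tibble(n = x$n, threshold = x$threshold,
                 n_significant = sum(x$significant),
                 n_flagged = sum(x$flagged))
}

#' @exportS3Method generics::tidy
tidy.slope_difference <- function(x, ...)
  dplyr::select(x$clusters, -dplyr::any_of("voxels"))

#' @exportS3Method generics::glance
glance.slope_difference <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, min_cluster = x$min_cluster,
                 connectivity = x$connectivity, n_clusters = nrow(x$clusters),
                 n_voxels = sum(x$clusters$size))
}

#' @exportS3Method generics::tidy
tidy.age_interaction <- function(x, ...) {
  out <- stat_map_tibble(x$tmap, "t_d")
  out$significant <- x$significant
  out
}

#' @exportS3Method generics::glance
glance.age_interaction <- function(x, ...) {
  tibble::tibble(n_tested = length(x$tested_cols), q = x$q,
                 n_significant = sum(x$significant),
                 max_abs_t_d = max(abs(x$fit$t_d[!x$fit$flagged])))
}

#' Plot axial slices of a statistic map
#'
#' A mosaic of axial (z) slices rendered with `geom_raster`; out-of-mask
#' voxels are blank.
#'
#' @param object a [stat_map()].
#' @param slices z indices to show (default: 6 evenly spaced in-mask slices).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stat_map <- function(object, slices = NULL, ...) {
  dm <- object$mask$dim
  if (is.null(slices)) {
    zin <- which(apply(object$mask$data, 3, any))
    slices <- unique(round(seq(min(zin), max(zin), length.out = 6)))
  }
  df <- purrr::map(slices, function(z) {
    sl <- object$data[, , z]
    tibble::tibble(i = rep(seq_len(dm[1]), dm[2]),
                   j = rep(seq_len(dm[2]), each = dm[1]),
                   z = z, value = as.vector(sl))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(name = object$statistic) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = object$contrast %||% object$statistic,
                  x = NULL, y = NULL)
}

#' Plot the permutation null distribution of maximal cluster size
#'
#' Histogram of the null maxima with observed cluster sizes overlaid.
#'
#' @param object a `perm_fwe` result.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_fwe <- function(object, ...) {
  df <- tibble::tibble(max_size = object$null_max_size)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$max_size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "maximal null cluster size (voxels)", y = "permutations",
                  title = sprintf("Cluster-FWE null (t > %g, %d permutations)",
                                  object$cluster_forming_t, object$n_perm))
  if (nrow(object$clusters) > 0)
    p <- p + ggplot2::geom_vline(xintercept = object$clusters$size,
                                 linetype = "dashed", colour = "firebrick")
  p
}
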