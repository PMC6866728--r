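# Volume and table IO: grey-matter volumes, masks, atlases, cohort stacks,
# statistic maps and cluster tables.

# ---- constructors -----------------------------------------------------------

#' Brain or ROI mask
#'
#' A binary mask on a voxel grid with its NIfTI affine.
#'
#' @param data logical or 0/1 numeric 3D array.
#' @param affine 4x4 voxel-index -> RAS mm transform.
#' @return object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine) {
  stopifnot(length(dim(data)) == 3)
  data <- array(as.logical(data), dim(data))
  if (anyNA(data)) stopf("mask contains missing values")
  affine <- unclass(as.matrix(affine))[1:4, 1:4]
  if (abs(det(affine)) < .Machine$double.eps) stopf("mask affine is singular")
  structure(list(data = data, affine = affine, dim = dim(data)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d in-mask voxels\n",
              paste(x$dim, collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Read a mask from a NIfTI file
#'
#' Voxels with value > 0.5 are in-mask.
#' @param path NIfTI file.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  brain_mask(as.array(img) > 0.5, RNifti::xform(img))
}

#' Write a mask to a NIfTI file
#' @param mask a [brain_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(array(as.numeric(mask$data), mask$dim), mask$affine, path)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Atlas label volume with a lookup table
#'
#' @param data integer 3D label array; 0 means unlabelled.
#' @param affine 4x4 affine.
#' @param lookup data frame with columns `id` and `name` covering every
#'   nonzero label present in `data`.
#' @export
atlas_labels <- function(data, affine, lookup) {
  stopifnot(length(dim(data)) == 3)
  data <- array(as.integer(round(data)), dim(data))
  lookup <- tibble::as_tibble(lookup)[, c("id", "name")]
  ids <- setdiff(sort(unique(as.vector(data))), 0L)
  missing <- setdiff(ids, lookup$id)
  if (length(missing) > 0)
    stopf("atlas labels missing from lookup: %s", paste(missing, collapse = ", "))
  structure(list(data = data, affine = unclass(as.matrix(affine)),
                 lookup = lookup, dim = dim(data)),
            class = "atlas_labels")
}

#' Read an atlas (label NIfTI + id,name CSV lookup)
#' @param volume_path NIfTI label volume.
#' @param lookup_path two-column CSV (`id`, `name`).
#' @export
read_atlas <- function(volume_path, lookup_path) {
  img <- RNifti::readNifti(volume_path)
  lookup <- utils::read.csv(lookup_path, stringsAsFactors = FALSE)
  atlas_labels(as.array(img), RNifti::xform(img), lookup)
}

atlas_name_at <- function(atlas, linear_idx) {
  if (is.null(atlas)) return(NA_character_)
  id <- atlas$data[linear_idx]
  ifelse(id == 0L, "unlabelled",
         atlas$lookup$name[match(id, atlas$lookup$id)])
}

# ---- cohort stack -----------------------------------------------------------

#' Construct a cohort stack from an in-memory value matrix
#'
#' The substrate of every voxel-wise fit: a subjects x in-mask-voxels matrix
#' of grey-matter density aligned with a subject table.
#'
#' @param values numeric matrix, one row per subject, one column per in-mask
#'   voxel (column order = increasing linear index over the mask).
#' @param mask a [brain_mask()].
#' @param subjects data frame of subject records, rows aligned with `values`.
#' @return object of class `gm_cohort`.
#' @export
gm_cohort <- function(values, mask, subjects) {
  stopifnot(inherits(mask, "brain_mask"))
  values <- as.matrix(values)
  voxel_idx <- which(mask$data)
  if (ncol(values) != length(voxel_idx))
    stopf("value matrix has %d columns but mask has %d voxels",
          ncol(values), length(voxel_idx))
  subjects <- tibble::as_tibble(subjects)
  if (nrow(values) != nrow(subjects))
    stopf("value matrix has %d rows but subject table has %d",
          nrow(values), nrow(subjects))
  if (anyNA(values)) stopf("cohort values contain NaN/NA")
  structure(list(values = values, mask = mask, voxel_idx = voxel_idx,
                 subjects = subjects),
            class = "gm_cohort")
}

#' @export
print.gm_cohort <- function(x, ...) {
  grp <- if ("group" %in% names(x$subjects)) {
    tb <- table(x$subjects$group)
    paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")
  } else "ungrouped"
  cat(sprintf("<gm_cohort> %d subjects (%s) x %d in-mask voxels on a %s grid\n",
              nrow(x$values), grp, ncol(x$values),
              paste(x$mask$dim, collapse = "x")))
  invisible(x)
}

#' @export
dim.gm_cohort <- function(x) dim(x$values)

#' Load a cohort of grey-matter volumes from disk
#'
#' Reads every volume named in the manifest, checks that it shares the mask's
#' grid and affine, and stacks the in-mask voxel values into a subjects x
#' voxels matrix aligned with the manifest rows.
#'
#' @param manifest data frame with a `path` column plus subject columns
#'   (`subject_id`, `group`, `age`, `sex`, ...).
#' @param mask a [brain_mask()] defining the analysis grid.
#' @return a [gm_cohort()].
#' @export
load_cohort <- function(manifest, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  manifest <- tibble::as_tibble(manifest)
  if (!"path" %in% names(manifest)) stopf("manifest must have a 'path' column")
  voxel_idx <- which(mask$data)
  values <- matrix(NA_real_, nrow(manifest), length(voxel_idx))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    img <- tryCatch(RNifti::readNifti(p),
                    error = function(e) stopf("cannot read volume '%s': %s",
                                              p, conditionMessage(e)))
    arr <- as.array(img)
    if (!identical(dim(arr), mask$dim))
      stopf("volume '%s' grid %s does not match mask grid %s", p,
            paste(dim(arr), collapse = "x"), paste(mask$dim, collapse = "x"))
    if (max(abs(RNifti::xform(img) - mask$affine)) > 1e-4)
      stopf("volume '%s' affine does not match the mask affine", p)
    v <- arr[voxel_idx]
    if (anyNA(v)) {
      who <- if ("subject_id" %in% names(manifest)) manifest$subject_id[i] else p
      stopf("volume for subject '%s' has NaN inside the mask", who)
    }
    values[i, ] <- v
  }
  gm_cohort(values, mask, manifest[setdiff(names(manifest), "path")])
}

#' Mean grey-matter density inside an ROI, per subject
#'
#' ROI voxels falling outside the cohort analysis mask are dropped with a
#' warning (seed masks derived from statistical maps can slightly exceed it).
#'
#' @param cohort a [gm_cohort()].
#' @param roi a [brain_mask()] on the same grid.
#' @return named numeric vector, one mean per subject.
#' @export
extract_roi_mean <- function(cohort, roi) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(roi, "brain_mask"))
  if (!identical(roi$dim, cohort$mask$dim))
    stopf("ROI grid does not match the cohort grid")
  roi_idx <- which(roi$data)
  cols <- match(roi_idx, cohort$voxel_idx)
  dropped <- sum(is.na(cols))
  if (dropped == length(roi_idx))
    stopf("ROI does not intersect the cohort mask")
  if (dropped > 0)
    warnf("%d of %d ROI voxels fall outside the cohort mask and were dropped",
          dropped, length(roi_idx))
  cols <- cols[!is.na(cols)]
  out <- rowMeans(cohort$values[, cols, drop = FALSE])
  if ("subject_id" %in% names(cohort$subjects))
    names(out) <- cohort$subjects$subject_id
  out
}

# ---- statistic maps ---------------------------------------------------------

#' Statistic map on the cohort grid
#'
#' Stores a per-voxel statistic (t, slope, correlation or p) as a full 3D
#' array with `NA` outside the mask.
#'
#' @param values numeric vector over in-mask voxels (aligned with the mask's
#'   increasing linear index order) or a full 3D array.
#' @param mask a [brain_mask()].
#' @param statistic label, e.g. `"t"`, `"slope"`, `"r"`.
#' @param df degrees of freedom, if applicable.
#' @param contrast free-text description of what the statistic tests.
#' @export
stat_map <- function(values, mask, statistic = "t", df = NULL, contrast = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  if (is.array(values) && length(dim(values)) == 3) {
    stopifnot(identical(dim(values), mask$dim))
    arr <- values
    arr[!mask$data] <- NA_real_
  } else {
    voxel_idx <- which(mask$data)
    stopifnot(length(values) == length(voxel_idx))
    arr <- array(NA_real_, mask$dim)
    arr[voxel_idx] <- values
  }
  structure(list(data = arr, mask = mask, statistic = statistic,
                 df = df, contrast = contrast),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$data[x$mask$data]
  cat(sprintf("<stat_map: %s> %s grid%s; in-mask range [%.3g, %.3g]\n",
              x$statistic, paste(x$mask$dim, collapse = "x"),
              if (!is.null(x$df)) sprintf(", df=%g", x$df) else "",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  if (!is.null(x$contrast)) cat("  contrast:", x$contrast, "\n")
  invisible(x)
}

#' In-mask values of a statistic map
#' @param map a [stat_map()].
#' @export
map_values <- function(map) map$data[map$mask$data]

#' Save a statistic map as NIfTI
#'
#' Out-of-mask voxels are written as NaN; a round-trip load reproduces the
#' in-mask values bit-exactly and preserves the affine.
#' @param map a [stat_map()].
#' @param path output path.
#' @export
save_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  write_nifti_array(map$data, map$mask$affine, path)
}

#' Read a statistic map saved with [save_stat_map()]
#'
#' @param path NIfTI file.
#' @param mask the analysis mask; defaults to the non-NaN voxels of the file.
#' @param statistic statistic label.
#' @export
read_stat_map <- function(path, mask = NULL, statistic = "t") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (is.null(mask)) mask <- brain_mask(!is.na(arr), RNifti::xform(img))
  stat_map(arr, mask, statistic = statistic)
}

# ---- cluster tables ---------------------------------------------------------

#' Label suprathreshold clusters in a statistic map
#'
#' Connected components of voxels with statistic strictly above `threshold`
#' under 6-, 18- or 26-neighbour connectivity.  The peak is the maximum-
#' statistic voxel (ties broken by smallest linear index); its world
#' coordinate comes from the affine and its anatomical label from the atlas.
#'
#' @param map a [stat_map()].
#' @param threshold cluster-forming statistic cutoff (strict).
#' @param connectivity 6, 18 or 26.
#' @param atlas optional [atlas_labels()] for peak naming.
#' @return tibble with one row per cluster: `cluster_id`, `size`,
#'   `peak_stat`, `peak_x/y/z` (mm), `peak_label`, plus a `voxels` list
#'   column of in-mask linear indices. Ordered by decreasing size.
#' @export
label_clusters <- function(map, threshold, connectivity = 26, atlas = NULL) {
  stopifnot(inherits(map, "stat_map"), is.finite(threshold))
  dimv <- map$mask$dim
  vals <- map$data
  idx <- which(!is.na(vals) & vals > threshold)
  empty <- tibble::tibble(cluster_id = integer(), size = integer(),
                          peak_stat = numeric(), peak_x = numeric(),
                          peak_y = numeric(), peak_z = numeric(),
                          peak_label = character(), voxels = list())
  if (length(idx) == 0) return(empty)
  memb <- connected_components(idx, dimv, connectivity)
  comp <- split(idx, memb)
  rows <- purrr::map(comp, function(vox) {
    v <- vals[vox]
    peak <- vox[which(v == max(v))[1]]   # ties -> smallest linear index
    mm <- voxel_to_mm(map$mask$affine, linear_to_ijk(peak, dimv) - 1)
    tibble::tibble(size = length(vox), peak_stat = max(v),
                   peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
                   peak_label = atlas_name_at(atlas, peak), voxels = list(vox))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$size), purrr::map_dbl(.data$voxels, 1))
  dplyr::bind_cols(tibble::tibble(cluster_id = seq_len(nrow(out))), out)[
    , c("cluster_id", "size", "peak_stat", "peak_x", "peak_y", "peak_z",
        "peak_label", "voxels")]
}

#' Export a cluster table as CSV (without the voxel list column)
#' @param clusters tibble from [label_clusters()].
#' @param path output CSV path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.csv(dplyr::select(clusters, -dplyr::any_of("voxels")),
                   path, row.names = FALSE)
  invisible(path)
}
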