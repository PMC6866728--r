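# Internal geometry and numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform
NULL

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))

#' Apply a NIfTI affine to 0-based voxel indices
#'
#' @param affine 4x4 voxel-index -> world (RAS mm) transform.
#' @param ijk matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @keywords internal
voxel_to_mm <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

# 1-based linear index <-> 1-based array index for a given dim
linear_to_ijk <- function(idx, dim) arrayInd(idx, dim)

ijk_to_linear <- function(ijk, dim) {
  (ijk[, 1]) + dim[1] * (ijk[, 2] - 1L) + dim[1] * dim[2] * (ijk[, 3] - 1L)
}

#' Default affine for a synthetic grid
#'
#' Isotropic voxels, grid centre at the world origin, RAS orientation.
#' @keywords internal
default_affine <- function(dim, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * dim / 2
  aff
}

#' Logical sphere on a voxel grid
#'
#' @param dim grid dimensions.
#' @param centre voxel-space centre (1-based, may be fractional).
#' @param radius radius in voxels.
#' @return logical 3D array.
#' @export
sphere_mask_array <- function(dim, centre, radius) {
  stopifnot(length(dim) == 3, length(centre) == 3, radius > 0)
  i <- seq_len(dim[1]); j <- seq_len(dim[2]); k <- seq_len(dim[3])
  d2 <- outer(outer((i - centre[1])^2, (j - centre[2])^2, `+`),
              (k - centre[3])^2, `+`)
  d2 <= radius^2
}

# Circulant 1D Gaussian kernel matrix (rows/cols sum to 1): convolution with
# wrap-around boundary, so the image sum is conserved exactly.
gaussian_circulant <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  x <- 0:(n - 1)
  d <- pmin(x, n - x)
  k <- exp(-d^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, ] <- k[((seq_len(n) - i) %% n) + 1]
  m
}

#' Smooth a 3D volume with an isotropic Gaussian kernel
#'
#' Separable convolution with circular (wrap-around) boundary handling, which
#' conserves the total image sum exactly. `sigma_mm` is the kernel standard
#' deviation in millimetres, matching the convention of VBM pipelines.
#'
#' @param vol 3D numeric array.
#' @param sigma_mm kernel standard deviation in mm.
#' @param voxel_mm voxel edge length in mm (isotropic).
#' @return smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, sigma_mm, voxel_mm = 2) {
  stopifnot(length(dim(vol)) == 3, sigma_mm >= 0, voxel_mm > 0)
  if (sigma_mm == 0) return(vol)
  dm <- dim(vol)
  sig <- sigma_mm / voxel_mm
  K1 <- gaussian_circulant(dm[1], sig)
  K2 <- if (dm[2] == dm[1]) K1 else gaussian_circulant(dm[2], sig)
  K3 <- if (dm[3] == dm[1]) K1 else gaussian_circulant(dm[3], sig)
  a <- K1 %*% matrix(vol, dm[1])
  a <- aperm(array(a, dm), c(2, 3, 1))
  a <- K2 %*% matrix(a, dm[2])
  a <- aperm(array(a, dm[c(2, 3, 1)]), c(2, 3, 1))
  a <- K3 %*% matrix(a, dm[3])
  aperm(array(a, dm[c(3, 1, 2)]), c(2, 3, 1))
}

# Connected components of a set of voxels (1-based linear indices) under
# 6/18/26 connectivity.  Returns an integer membership vector parallel to idx.
connected_components <- function(idx, dim, connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  n <- length(idx)
  if (n == 0) return(integer(0))
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  off <- switch(connectivity,
    "6"  = off[nz == 1, , drop = FALSE],
    "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
    "26" = off[nz >= 1, , drop = FALSE])
  ijk <- linear_to_ijk(idx, dim)
  edges <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim[3]
    if (!any(ok)) next
    j <- match(ijk_to_linear(nb[ok, , drop = FALSE], dim), idx)
    hit <- !is.na(j)
    if (any(hit)) edges[[o]] <- cbind(which(ok)[hit], j[hit])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::make_graph(edges = t(edges), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Deterministic child seeds derived from a master seed (kept below 2^31).
derive_seeds <- function(master, n) {
  (as.integer(master) + 1000003L * seq_len(n)) %% 2147480989L
}
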