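# Independent oracles and fixture builders used across the suite.
# Every oracle is a deliberately naive, textbook implementation that shares
# no code with the package internals it checks.

# Long-hand OLS contrast t via the normal equations, one voxel at a time.
oracle_ols_t <- function(Y, X, contrast) {
  apply(as.matrix(Y), 2, function(y) {
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    s2 <- sum(res^2) / df
    cv <- t(contrast) %*% solve(XtX) %*% contrast
    drop(t(contrast) %*% beta) / sqrt(s2 * drop(cv))
  })
}

# Textbook Pearson correlation from sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Benjamini-Hochberg step-up evaluated directly from its definition:
# reject H_(1)..H_(k) for the largest k with p_(k) <= k*q/m.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Equal-variance two-sample t from the pooled-variance formula.
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Circular Gaussian smoothing through R's FFT: an algorithmically independent
# implementation of the generator's separable circulant convolution.
oracle_smooth_fft <- function(vol, sigma_vox) {
  dm <- dim(vol)
  k1 <- function(n) {
    x <- 0:(n - 1); d <- pmin(x, n - x)
    k <- exp(-d^2 / (2 * sigma_vox^2)); k / sum(k)
  }
  ker <- outer(outer(k1(dm[1]), k1(dm[2])), k1(dm[3]))
  Re(fft(fft(vol) * fft(ker), inverse = TRUE)) / prod(dm)
}

dice_coef <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Tiny cohort from an explicit subjects x voxels matrix on an all-true grid.
toy_cohort <- function(values, dim = NULL, subjects = NULL, voxel_mm = 2) {
  values <- as.matrix(values)
  if (is.null(dim)) dim <- c(ncol(values), 1L, 1L)
  mask <- brain_mask(array(TRUE, dim), default_affine(dim, voxel_mm))
  if (is.null(subjects)) {
    n <- nrow(values)
    subjects <- tibble::tibble(
      subject_id = sprintf("T%02d", seq_len(n)),
      group = rep(c("control", "pd"), length.out = n),
      age = seq(50, 70, length.out = n) +
        rep(c(0.7, -1.3, 2.1, -0.4), length.out = n),
      sex = rep(c("F", "M", "M", "F"), length.out = n))
  }
  gm_cohort(values, mask, subjects)
}

# Small default-geometry synthetic config for fast tests.
quick_config <- function(...) {
  synth_config(n_control = 12, n_pd = 16, seed = 42, ...)
}
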