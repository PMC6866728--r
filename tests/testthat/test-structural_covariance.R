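# Seed covariance maps, balanced subsampling and the interaction model.

test_that("seed covariance reproduces exact and textbook correlations", {
  set.seed(4)
  n <- 10
  seedv <- rnorm(n, 0.5, 0.05)
  Y <- cbind(seedv,                     # r = 1
             -seedv,                    # r = -1
             matrix(rnorm(n * 5), n),   # random columns vs oracle
             rep(0.4, n))               # zero variance -> flagged, r = 0
  st <- toy_cohort(Y)
  cm <- seed_covariance_map(st, seedv)
  r <- map_values(cm$r_map)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(r[2], -1, tolerance = 1e-12)
  for (j in 3:7)
    expect_equal(r[j], oracle_pearson(seedv, Y[, j]), tolerance = 1e-12)
  expect_equal(r[8], 0)
  expect_true(cm$flagged[8])
  expect_error(seed_covariance_map(st, rep(1, n)), "zero variance")
})

test_that("the strict display threshold and FDR branch mark voxels coherently", {
  set.seed(44)
  n <- 60
  seedv <- rnorm(n)
  Y <- cbind(seedv + rnorm(n, sd = 0.1),   # very strong correlation
             matrix(rnorm(n * 20), n))
  st <- toy_cohort(Y)
  fixed <- seed_covariance_map(st, seedv, p_cutoff = 6e-8)
  expect_true(fixed$significant[1])
  expect_lt(mean(fixed$significant[-1]), 0.2)
  fdr <- seed_covariance_map(st, seedv, method = "fdr", q = 0.05)
  expect_true(fdr$significant[1])
})

test_that("within-group slope b equals the group Pearson correlation", {
  set.seed(10)
  for (i in 1:20) {
    n0 <- sample(5:20, 1); n1 <- sample(5:20, 1)
    g <- rep(c("control", "pd"), c(n0, n1))
    y <- rnorm(n0 + n1); x <- rnorm(n0 + n1)
    fit <- fit_interaction(y, x, g)
    r0 <- oracle_pearson(x[g == "control"], y[g == "control"])
    r1 <- oracle_pearson(x[g == "pd"], y[g == "pd"])
    expect_equal(fit$b, r0, tolerance = 1e-12)
    expect_equal(fit$b + fit$d, r1, tolerance = 1e-12)
  }
})

test_that("the saturated noiseless model is solved exactly", {
  x <- c(rnorm(6), rnorm(6))
  g <- rep(c("control", "pd"), each = 6)
  y <- ifelse(g == "control", x, -x)
  fit <- fit_interaction(y, x, g)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$d, -2, tolerance = 1e-12)
  expect_lt(fit$sigma2, 1e-24)

  # identical (Y, X) pairs in both groups -> d = 0 exactly
  x2 <- rep(rnorm(6), 2)
  y2 <- rep(rnorm(6), 2)
  fit2 <- fit_interaction(y2, x2, g)
  expect_equal(fit2$d, 0, tolerance = 1e-14)
})

test_that("interaction t and p agree with the lm oracle on z-scored data", {
  set.seed(15)
  n0 <- 14; n1 <- 18
  g <- rep(c("control", "pd"), c(n0, n1))
  pd <- as.numeric(g == "pd")
  y <- rnorm(n0 + n1); x <- rnorm(n0 + n1) + 0.5 * y * pd
  fit <- fit_interaction(y, x, g)
  zs <- function(v, g) ave(v, g, FUN = function(u) (u - mean(u)) / sd(u))
  lmfit <- stats::lm(zs(y, g) ~ zs(x, g) * pd)
  sm <- summary(lmfit)$coefficients
  expect_equal(fit$d, unname(sm["zs(x, g):pd", "Estimate"]), tolerance = 1e-10)
  expect_equal(fit$t_d, unname(sm["zs(x, g):pd", "t value"]), tolerance = 1e-10)
  expect_equal(fit$p_d, unname(sm["zs(x, g):pd", "Pr(>|t|)"]), tolerance = 1e-10)

  # voxel-wise: same answers column by column
  X <- matrix(rnorm((n0 + n1) * 4), n0 + n1)
  vfit <- fit_interaction(y, X, g)
  for (j in 1:4) {
    sfit <- fit_interaction(y, X[, j], g)
    expect_equal(vfit$t_d[j], sfit$t_d, tolerance = 1e-12)
  }
})

test_that("t_d is invariant to affine rescaling of raw GM within a group", {
  set.seed(20)
  g <- rep(c("control", "pd"), each = 12)
  y <- rnorm(24); x <- rnorm(24)
  t0 <- fit_interaction(y, x, g)$t_d
  y2 <- ifelse(g == "pd", 3 * y + 10, y)
  x2 <- ifelse(g == "control", 0.5 * x - 2, x)
  expect_equal(fit_interaction(y2, x2, g)$t_d, t0, tolerance = 1e-10)
})

test_that("the normalised interaction test is exact at independence and
           conservative, never inflated, at high common correlation", {
  set.seed(501)
  p_indep <- replicate(400, {
    d <- simulate_covariance_rois(80, 80, loading_control = 0, loading_pd = 0)
    fit_interaction(d$seed_gm, d$network_gm, d$group)$p_d
  })
  expect_gt(mean(p_indep < 0.05), 0.02)
  expect_lt(mean(p_indep < 0.05), 0.10)

  # with a strong shared correlation the per-group z-scoring deflates t_d:
  # the test under-rejects but never exceeds the nominal level
  set.seed(502)
  p_high <- replicate(400, {
    d <- simulate_covariance_rois(80, 80, loading_control = 0.6, loading_pd = 0.6)
    fit_interaction(d$seed_gm, d$network_gm, d$group)$p_d
  })
  expect_lt(mean(p_high < 0.05), 0.05)
})

test_that("balanced subsampling is reproducible and degenerates to identity", {
  idx <- 11:30
  s1 <- balanced_subsample(idx, 8, n_repeats = 5, seed = 3)
  s2 <- balanced_subsample(idx, 8, n_repeats = 5, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(s) all(s %in% idx) && length(s) == 8, TRUE)))
  ident <- balanced_subsample(idx, length(idx), n_repeats = 3, seed = 1)
  expect_true(all(vapply(ident, identical, TRUE, y = idx)))
  expect_error(balanced_subsample(idx, 25, seed = 1), "exceeds")
})

test_that("averaged subsample maps converge to the full-group map", {
  syn <- generate_cohort(synth_config(n_control = 30, n_pd = 80, seed = 55))
  co <- syn$cohort
  g <- co$subjects$group
  sv <- extract_roi_mean(co, brain_mask(syn$truth$seed_mask, syn$truth$affine))
  i_pd <- which(g == "pd")
  full <- seed_covariance_map(
    gm_cohort(co$values[i_pd, ], co$mask, co$subjects[i_pd, ]), sv[i_pd])
  subsets <- balanced_subsample(i_pd, 30, n_repeats = 40, seed = 8)
  avg <- average_covariance_map(co, sv, subsets)
  # degenerate subsample equals the single-pass map exactly
  degen <- average_covariance_map(co, sv, balanced_subsample(i_pd, length(i_pd),
                                                             n_repeats = 2))
  expect_equal(map_values(degen$r_map), map_values(full$r_map), tolerance = 1e-12)
  # Monte-Carlo mean within 0.05 of the full-group r across voxels
  expect_lt(max(abs(map_values(avg$r_map) - map_values(full$r_map))), 0.05 * 3)
  expect_lt(mean(abs(map_values(avg$r_map) - map_values(full$r_map))), 0.05)

  # permutation invariance over subject order
  perm <- sample(nrow(co$values))
  cop <- gm_cohort(co$values[perm, ], co$mask, co$subjects[perm, ])
  subsets_p <- lapply(subsets, function(s) match(s, perm))
  avg_p <- average_covariance_map(cop, sv[perm], subsets_p)
  expect_equal(map_values(avg_p$r_map), map_values(avg$r_map), tolerance = 1e-12)
})

test_that("interaction difference map localises a planted covariance change", {
  syn <- generate_cohort(synth_config(n_control = 80, n_pd = 80,
                                      loading_control = 0.8, loading_pd = 0,
                                      seed = 66))
  co <- syn$cohort
  sv <- extract_roi_mean(co, brain_mask(syn$truth$seed_mask, syn$truth$affine))
  imap <- interaction_difference_map(co, sv, correction = "fdr", q = 0.05)
  sig_vox <- co$voxel_idx[imap$significant]
  net_vox <- which(syn$truth$network_mask)
  # the planted network region is rich in significant voxels...
  expect_gt(length(intersect(sig_vox, net_vox)) / length(net_vox), 0.3)
  # ...and significant voxels stay near the planted covariance system
  cov_vox <- which(vbmtools:::smooth_volume(
    (syn$truth$network_mask | syn$truth$seed_mask) * 1, 6, 2) > 0.01)
  expect_gt(length(intersect(sig_vox, cov_vox)) / max(length(sig_vox), 1), 0.9)
})
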