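# Voxel-wise GLM, permutation cluster-FWE, uncorrected maps, FDR and
# severity subgrouping.

make_subjects <- function(n, groups, ages = NULL, sexes = NULL) {
  tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)),
                 group = groups,
                 age = ages %||%
                   (seq(50, 70, length.out = n) +
                      rep(c(0.7, -1.3, 2.1, -0.4), length.out = n)),
                 sex = sexes %||% rep(c("F", "M", "M", "F"), length.out = n))
}

test_that("design matrix codes groups/sex and rejects rank deficiency", {
  s <- make_subjects(4, c("control", "control", "pd", "pd"))
  d <- build_design_matrix(s, covariates = character(0))
  expect_equal(dim(d$X), c(4L, 2L))
  expect_equal(unname(d$X[, "group"]), c(0, 0, 1, 1))
  expect_equal(qr(d$X)$rank, 2L)

  d2 <- build_design_matrix(s)
  expect_equal(d2$columns, c("intercept", "group", "age", "sex"))
  expect_equal(unname(d2$X[, "sex"]), c(0, 1, 1, 0))

  same_sex <- make_subjects(4, c("control", "control", "pd", "pd"),
                            sexes = rep("F", 4))
  expect_error(build_design_matrix(same_sex), "sex")
  s_na <- s; s_na$age[2] <- NA
  expect_error(build_design_matrix(s_na), "missing")
})

test_that("voxel-wise GLM t matches the long-hand OLS oracle to 1e-8", {
  set.seed(101)
  n <- 6; V <- 10
  Y <- matrix(rnorm(n * V, 0.5, 0.1), n)
  subjects <- make_subjects(n, rep(c("control", "pd"), each = 3),
                            ages = c(51, 63, 58, 70, 49, 66))
  st <- toy_cohort(Y, subjects = subjects)
  design <- build_design_matrix(subjects)
  fit <- fit_voxelwise_glm(st, design)
  want <- oracle_ols_t(Y, design$X, design$contrast)
  expect_equal(map_values(fit$tmap), unname(want), tolerance = 1e-8)
  expect_equal(fit$df, n - 4L)
})

test_that("group t is invariant to constant shifts and to centring age", {
  set.seed(5)
  n <- 12
  Y <- matrix(rnorm(n * 6, 0.5, 0.05), n)
  subjects <- make_subjects(n, rep(c("control", "pd"), each = 6))
  st <- toy_cohort(Y, subjects = subjects)
  design <- build_design_matrix(subjects)
  t0 <- map_values(fit_voxelwise_glm(st, design)$tmap)

  st_shift <- toy_cohort(Y + 5, subjects = subjects)
  expect_equal(map_values(fit_voxelwise_glm(st_shift, design)$tmap), t0,
               tolerance = 1e-10)

  centred <- subjects; centred$age <- centred$age - mean(centred$age)
  dc <- build_design_matrix(centred)
  expect_equal(map_values(fit_voxelwise_glm(st, dc)$tmap), t0,
               tolerance = 1e-10)
})

test_that("identical group data gives t = 0 with a zero-variance flag", {
  Y <- matrix(0.4, 6, 3)
  Y[, 2] <- rnorm(6)
  subjects <- make_subjects(6, rep(c("control", "pd"), each = 3))
  st <- toy_cohort(Y, subjects = subjects)
  fit <- fit_voxelwise_glm(st, build_design_matrix(subjects, character(0)))
  expect_equal(map_values(fit$tmap)[1], 0)
  expect_true(fit$flagged[1])
  expect_false(fit$flagged[2])
})

test_that("small two-group designs enumerate all relabelings exhaustively", {
  set.seed(77)
  n <- 8; V <- 12
  Y <- matrix(rnorm(n * V), n)
  Y[1:4, 5:7] <- Y[1:4, 5:7] + 2.2   # planted strip in the control half
  subjects <- make_subjects(n, rep(c("control", "pd"), each = 4))
  st <- toy_cohort(Y, subjects = subjects)
  design <- build_design_matrix(subjects, character(0))
  res <- permutation_cluster_fwe(st, design, cluster_forming_t = 1.5,
                                 n_perm = 500, connectivity = 6)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(8, 4))
  expect_true(all(res$clusters$p_corrected >= 1 / choose(8, 4)))

  # independent brute force: every C(8,4) relabeling, pooled t per voxel,
  # run-length clusters on the 1D strip
  combs <- combn(8, 4)
  null_max <- apply(combs, 2, function(ones) {
    tt <- vapply(seq_len(V), function(v)
      oracle_pooled_t(Y[ones, v], Y[-ones, v]), 0)
    supra <- tt > 1.5
    if (!any(supra)) return(0L)
    max(rle(supra)$lengths[rle(supra)$values])
  })
  for (i in seq_len(nrow(res$clusters)))
    expect_equal(res$clusters$p_corrected[i],
                 mean(null_max >= res$clusters$size[i]))
})

test_that("a vacuous cluster-forming threshold yields an empty cluster set", {
  set.seed(3)
  Y <- matrix(rnorm(10 * 8), 10)
  subjects <- make_subjects(10, rep(c("control", "pd"), each = 5))
  st <- toy_cohort(Y, subjects = subjects)
  design <- build_design_matrix(subjects, character(0))
  res <- suppressWarnings(
    permutation_cluster_fwe(st, design, cluster_forming_t = 1e6, n_perm = 120))
  expect_equal(nrow(res$clusters), 0L)
})

test_that("corrected p is invariant to subject order and global image shifts", {
  set.seed(8)
  n <- 10; V <- 30
  Y <- matrix(rnorm(n * V), n)
  Y[6:10, 10:14] <- Y[6:10, 10:14] - 1.5
  subjects <- make_subjects(n, rep(c("control", "pd"), each = 5))
  st <- toy_cohort(Y, subjects = subjects)
  design <- build_design_matrix(subjects, character(0))
  base <- permutation_cluster_fwe(st, design, cluster_forming_t = 1.2,
                                  n_perm = 400, connectivity = 6)
  expect_true(base$exhaustive)   # C(10,5) = 252 <= 400

  perm <- sample(n)
  stp <- toy_cohort(Y[perm, ], subjects = subjects[perm, ])
  shuffled <- permutation_cluster_fwe(stp, build_design_matrix(subjects[perm, ],
                                                               character(0)),
                                      cluster_forming_t = 1.2, n_perm = 400,
                                      connectivity = 6)
  expect_equal(sort(base$clusters$p_corrected),
               sort(shuffled$clusters$p_corrected))

  sts <- toy_cohort(Y + 3, subjects = subjects)
  shifted <- permutation_cluster_fwe(sts, design, cluster_forming_t = 1.2,
                                     n_perm = 400, connectivity = 6)
  expect_equal(base$clusters$p_corrected, shifted$clusters$p_corrected)
})

test_that("uncorrected map applies the pooled-variance two-sample t", {
  set.seed(12)
  x1 <- rnorm(5, 0.6, 0.05); x2 <- rnorm(5, 0.4, 0.05)
  Y <- cbind(c(x1, x2))
  subjects <- make_subjects(10, rep(c("control", "pd"), each = 5))
  st <- toy_cohort(Y, subjects = subjects)
  res <- uncorrected_tmap(st)
  expect_equal(map_values(res$tmap), oracle_pooled_t(x1, x2), tolerance = 1e-10)
  # default operating point: t > 2.8 and two-sided p < 0.005
  expect_equal(res$t_threshold, 2.8)
  expect_equal(res$p_threshold, 0.005)
  expect_equal(res$threshold, max(2.8, qt(1 - 0.005 / 2, 8)))
  expect_true(all(res$clusters$correction == "uncorrected"))

  # identical groups: nothing survives
  Yn <- cbind(rep(0.5, 10)) + cbind(rnorm(10, sd = 1e-3))
  same <- uncorrected_tmap(toy_cohort(Yn[c(1:5, 1:5), , drop = FALSE],
                                      subjects = subjects))
  expect_equal(nrow(same$clusters), 0L)

  one_group <- make_subjects(4, rep("pd", 4))
  expect_error(uncorrected_tmap(toy_cohort(matrix(rnorm(8), 4),
                                           subjects = one_group)),
               "group")
})

test_that("BH-FDR matches the step-up definition and handles edge cases", {
  # worked example by hand: m = 4, q = 0.05
  # thresholds k*q/m = 0.0125, 0.025, 0.0375, 0.05
  # p_(3) = 0.02 <= 3*0.05/4 = 0.0375, so the first three are rejected
  got <- fdr_correct(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
  expect_equal(got$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(got$significant, oracle_bh_reject(c(0.001, 0.01, 0.02, 0.9), 0.05))

  expect_false(any(fdr_correct(rep(1, 20))$significant))
  expect_true(fdr_correct(0.01, q = 0.05)$significant)

  expect_warning(withNA <- fdr_correct(c(0.01, NA, 0.5)), "NaN")
  expect_true(is.na(withNA$p_adjusted[2]))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")

  # adjusted p monotone non-decreasing in raw-p rank
  set.seed(2)
  p <- runif(50)
  adj <- fdr_correct(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("severity split follows the at-or-above rule and reports missing", {
  s <- tibble::tibble(subject_id = c("a", "b", "c"),
                      updrs3 = c(10, 30, NA))
  expect_message(sp <- median_split(s), "1 subjects excluded")
  expect_equal(as.character(sp$severity), c("mild", "moderate"))
  expect_equal(attr(sp, "n_missing"), 1L)

  # a score exactly at the threshold goes to the moderate side
  at21 <- median_split(tibble::tibble(updrs3 = 21))
  expect_equal(as.character(at21$severity), "moderate")

  # median threshold on distinct scores gives a near-even partition
  set.seed(6)
  sc <- sample(seq_len(1000), 101)
  sp2 <- median_split(tibble::tibble(updrs3 = sc), threshold = median(sc))
  expect_lte(abs(sum(sp2$severity == "mild") - sum(sp2$severity == "moderate")), 1L)
})
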