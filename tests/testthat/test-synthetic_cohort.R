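# The synthetic cohort generator: determinism, planted-effect recovery and
# agreement with independent oracles of the same generative model.

test_that("noise-free, effect-free cohorts are identical smoothed baselines", {
  cfg <- synth_config(n_control = 3, n_pd = 3, noise_sd = 0,
                      atrophy_frac = 0, slope_control = 0, slope_pd = 0,
                      loading_control = 0, loading_pd = 0,
                      clinical_noise_sd = 0, missing_rate = 0, seed = 9)
  syn <- generate_cohort(cfg)
  vals <- syn$cohort$values
  for (i in 2:nrow(vals)) expect_equal(vals[i, ], vals[1, ], tolerance = 0)
  # equals the smoothed baseline (independent FFT smoother), clipped at 0
  base <- cfg$baseline * syn$truth$brain_mask
  sm <- oracle_smooth_fft(base, cfg$smooth_sigma_mm / cfg$voxel_mm)
  sm[sm < 0] <- 0
  expect_equal(vals[1, ], sm[syn$cohort$voxel_idx], tolerance = 1e-10)
})

test_that("the same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(quick_config())
  b <- generate_cohort(quick_config())
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$clinical, b$clinical)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_control = 1), "at least 2")
  expect_error(synth_config(loading_control = 1.2), "loadings")
  expect_error(synth_config(noise_sd = -0.1), "noise")
  expect_error(synth_config(age_range = c(70, 60)), "age range")
  bad_clin <- default_clinical_scores()
  bad_clin$target_r[1] <- 1
  expect_error(synth_config(clinical = bad_clin), "correlation")
  regs <- default_regions(); regs$radius[1] <- 0
  expect_error(synth_config(regions = regs), "radii")
})

test_that("smoothing conserves the image sum and matches the FFT oracle", {
  set.seed(21)
  vol <- array(rnorm(16^3, 0.5, 0.2), c(16, 16, 16))
  sm <- smooth_volume(vol, 3, 2)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-6)
  expect_equal(sm, oracle_smooth_fft(vol, 1.5), tolerance = 1e-10)
  expect_identical(smooth_volume(vol, 0, 2), vol)
})

test_that("planted atrophy and age slopes are recoverable from region means", {
  cfg <- synth_config(n_control = 60, n_pd = 60, seed = 5)
  syn <- generate_cohort(cfg)
  g <- syn$cohort$subjects$group
  sig_vox <- cfg$smooth_sigma_mm / cfg$voxel_mm
  region_attn <- function(mask_arr) {
    w <- oracle_smooth_fft(mask_arr / 1, sig_vox)
    mean(w[which(mask_arr)])   # smoothing scales an in-region step by this
  }

  am <- brain_mask(syn$truth$atrophy_mask, syn$truth$affine)
  m <- extract_roi_mean(syn$cohort, am)
  diff <- mean(m[g == "control"]) - mean(m[g == "pd"])
  sem <- sqrt(stats::var(m[g == "control"]) / 60 + stats::var(m[g == "pd"]) / 60)
  expected <- cfg$atrophy_frac * cfg$baseline * region_attn(syn$truth$atrophy_mask)
  expect_lt(abs(diff - expected), 2 * sem)

  agem <- extract_roi_mean(syn$cohort, brain_mask(syn$truth$age_mask, syn$truth$affine))
  attn_age <- region_attn(syn$truth$age_mask)
  for (lev in c("control", "pd")) {
    rows <- which(g == lev)
    fit <- stats::lm(agem[rows] ~ syn$cohort$subjects$age[rows])
    slope <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(slope - syn$truth$slopes[[lev]] * attn_age), 2 * se)
  }
})

test_that("planted covariance matches a first-principles oracle of the model", {
  # Implementation path: volume generator at n = 200/group.
  cfg <- synth_config(n_control = 200, n_pd = 200,
                      loading_control = 0.6, loading_pd = 0.6, seed = 31)
  syn <- generate_cohort(cfg)
  g <- syn$cohort$subjects$group
  sv <- extract_roi_mean(syn$cohort, brain_mask(syn$truth$seed_mask, syn$truth$affine))
  nv <- extract_roi_mean(syn$cohort, brain_mask(syn$truth$network_mask, syn$truth$affine))
  r_obs <- c(oracle_pearson(sv[g == "control"], nv[g == "control"]),
             oracle_pearson(sv[g == "pd"], nv[g == "pd"]))

  # Oracle: the same latent-factor model at ROI granularity, with the
  # region-mean signal attenuation and region-mean noise sd derived from the
  # smoothing kernel by first principles (independent FFT smoother), then a
  # large-n scalar Monte-Carlo run.
  sig_vox <- cfg$smooth_sigma_mm / cfg$voxel_mm
  region_stats <- function(mask_arr) {
    w <- oracle_smooth_fft(mask_arr / 1, sig_vox)        # smoothed indicator
    idx <- which(mask_arr)
    attn <- mean(w[idx])                                 # signal attenuation
    # region mean of smoothed white noise: weights = smoothed averaging kernel
    avg <- array(0, dim(mask_arr)); avg[idx] <- 1 / length(idx)
    wts <- oracle_smooth_fft(avg, sig_vox)
    list(attn = attn, noise_sd = cfg$noise_sd * sqrt(sum(wts^2)))
  }
  s_seed <- region_stats(syn$truth$seed_mask)
  s_net <- region_stats(syn$truth$network_mask)
  set.seed(99)
  nmc <- 1e5
  z <- rnorm(nmc)
  lam <- 0.6 * cfg$latent_scale
  seed_mc <- lam * s_seed$attn * z + rnorm(nmc, sd = s_seed$noise_sd)
  net_mc <- lam * s_net$attn * z + rnorm(nmc, sd = s_net$noise_sd)
  r_oracle <- oracle_pearson(seed_mc, net_mc)
  expect_lt(abs(r_obs[1] - r_oracle), 0.1)
  expect_lt(abs(r_obs[2] - r_oracle), 0.1)
})

test_that("clinical scores hit their requested marginal correlation", {
  subjects <- tibble::tibble(subject_id = sprintf("S%03d", 1:300),
                             age = runif(300, 45, 80),
                             scan_date = as.Date("2015-06-01") + 1:300)
  # requested -0.3 at n = 300 -> recovered within +-0.1 (visit 1, no missing)
  clin <- tibble::tibble(score = "scopa_aut", mean = 9.3, sd = 6.7,
                         target_r = -0.3, age_coef = 0)
  cfg <- synth_config(clinical = clin, clinical_noise_sd = 0, missing_rate = 0)
  set.seed(17)
  seedgm <- rnorm(300, 0.5, 0.03)
  tbl <- generate_clinical_scores(seedgm, cfg, subjects)
  v1 <- tbl[tbl$visit == 1, ]
  expect_equal(v1$subject_id, subjects$subject_id)
  expect_lt(abs(oracle_pearson(seedgm, v1$value) - (-0.3)), 0.1)

  # requested 0 -> |r| < 0.15 at n = 300 in at least 95 of 100 runs
  clin0 <- clin; clin0$target_r <- 0
  cfg0 <- synth_config(clinical = clin0, clinical_noise_sd = 0, missing_rate = 0)
  set.seed(18)
  hits <- sum(replicate(100, {
    tb <- generate_clinical_scores(seedgm, cfg0, subjects)
    abs(oracle_pearson(seedgm, tb$value[tb$visit == 1])) < 0.15
  }))
  expect_gte(hits, 95)

  # near-noiseless limit: requested correlation ~1 is recovered ~exactly
  clin1 <- clin; clin1$target_r <- 0.999
  cfg1 <- synth_config(clinical = clin1, clinical_noise_sd = 0, missing_rate = 0)
  tb1 <- generate_clinical_scores(seedgm, cfg1, subjects)
  expect_gt(oracle_pearson(seedgm, tb1$value[tb1$visit == 1]), 0.99)

  # requesting |r| >= 1 errors
  clin_bad <- clin; clin_bad$target_r <- -1
  cfg_b <- cfg; cfg_b$clinical <- clin_bad
  expect_error(generate_clinical_scores(seedgm, cfg_b, subjects), "correlation")
})

test_that("written cohorts reload identically through the manifest", {
  dir <- withr::local_tempdir()
  syn <- generate_cohort(quick_config(), dir = dir)
  manifest <- utils::read.csv(syn$paths$manifest, stringsAsFactors = FALSE)
  mask <- read_mask(syn$paths$mask)
  st <- load_cohort(manifest, mask)
  expect_equal(st$values, syn$cohort$values, tolerance = 0)
  atl <- read_atlas(syn$paths$atlas_volume, syn$paths$atlas_lookup)
  expect_setequal(atl$lookup$name, default_regions()$name)
})
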