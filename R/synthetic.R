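# Synthetic cohort generator: reproducible grey-matter phantoms with the
# statistical structure every downstream stage assumes — a focal group
# atrophy effect, group-specific linear age decline, a seed-anchored
# covariance network with group-dependent loading, and clinical scores
# correlated with seed grey matter.

#' Default region layout for the synthetic brain phantom
#'
#' Four well-separated spheres inside the brain sphere: an atrophy target
#' that doubles as the covariance seed (mimicking a seed extracted from the
#' group VBM result), a distant network node, and a region of accelerated
#' age-related decline.
#'
#' @return tibble with columns `name`, `cx`, `cy`, `cz` (1-based voxel
#'   centre), `radius` (voxels) and `role`.
#' @export
default_regions <- function() {
  tibble::tribble(
    ~name,              ~cx, ~cy, ~cz, ~radius, ~role,
    "amygdala_R",        23,  16,  12,       4, "atrophy",
    "amygdala_R_seed",   23,  16,  12,       4, "seed",
    "thalamus_L",        10,  16,  12,       4, "covariance_network",
    "hippocampus_R",     16,  17,  23,       5, "age_slope"
  )
}

#' Default clinical score generators
#'
#' Score scales follow the instruments' usual ranges; `target_r` is the
#' marginal correlation between the score and seed grey matter that the
#' generator plants (positive for preserved function scores, negative for
#' symptom burden).
#' @export
default_clinical_scores <- function() {
  tibble::tribble(
    ~score,        ~mean,  ~sd, ~target_r, ~age_coef,
    "updrs1",       4.88, 3.30,    -0.111,         0,
    "updrs2",       7.94, 4.76,         0,         0,
    "updrs3",      21.60, 9.71,         0,         0,
    "gds",          4.27, 1.55,         0,         0,
    "ess",          7.17, 4.13,         0,         0,
    "hvlt",        46.75, 7.72,     0.155,         0,
    "scopa_aut",    9.28, 6.73,     -0.15,         0,
    "stai_state",  33.60, 10.64,        0,         0,
    "stai_trait",  35.24, 7.25,         0,         0
  )
}

#' Configuration for a synthetic grey-matter cohort
#'
#' The full recipe — geometry, group sizes, planted effects, noise, smoothing
#' and RNG seed — for a reproducible cohort of modulated-and-smoothed
#' grey-matter density phantoms.
#'
#' @param dim grid dimensions (3 integers).
#' @param voxel_mm isotropic voxel size in mm.
#' @param n_control,n_pd group sizes (each >= 2).
#' @param age_range uniform age range in years.
#' @param prop_male probability a subject is male.
#' @param baseline grey-matter density inside the brain sphere.
#' @param brain_radius brain sphere radius in voxels (defines the analysis mask).
#' @param noise_sd per-voxel noise standard deviation before smoothing.
#' @param smooth_sigma_mm Gaussian smoothing sigma in mm.
#' @param regions region table as in [default_regions()].
#' @param atrophy_frac fractional grey-matter reduction in the atrophy region
#'   for the PD group.
#' @param slope_control,slope_pd linear age slope (GM-units/year) planted in
#'   the `age_slope` region for each group.
#' @param age_ref centring age for the planted decline.
#' @param loading_control,loading_pd latent-factor loading (in \[-1, 1\]) tying
#'   seed and network regions together within each group.
#' @param latent_scale amplitude (GM units) of the shared latent factor.
#' @param clinical clinical score table as in [default_clinical_scores()].
#' @param clinical_noise_sd within-subject visit-to-visit score noise (as a
#'   fraction of the score sd).
#' @param missing_rate probability a clinical value is missing at a visit.
#' @param seed RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(dim = c(32L, 32L, 32L), voxel_mm = 2,
                         n_control = 172, n_pd = 366,
                         age_range = c(45, 80), prop_male = 0.64,
                         baseline = 0.55, brain_radius = 13,
                         noise_sd = 0.35, smooth_sigma_mm = 3,
                         regions = default_regions(),
                         atrophy_frac = 0.08,
                         slope_control = -0.001234, slope_pd = -0.004434,
                         age_ref = 62,
                         loading_control = 0.6, loading_pd = 0,
                         latent_scale = 0.05,
                         clinical = default_clinical_scores(),
                         clinical_noise_sd = 0.1, missing_rate = 0.05,
                         seed = 1L) {
  cfg <- list(dim = as.integer(dim), voxel_mm = voxel_mm,
              n_control = as.integer(n_control), n_pd = as.integer(n_pd),
              age_range = age_range, prop_male = prop_male,
              baseline = baseline, brain_radius = brain_radius,
              noise_sd = noise_sd, smooth_sigma_mm = smooth_sigma_mm,
              regions = tibble::as_tibble(regions),
              atrophy_frac = atrophy_frac,
              slope_control = slope_control, slope_pd = slope_pd,
              age_ref = age_ref,
              loading_control = loading_control, loading_pd = loading_pd,
              latent_scale = latent_scale,
              clinical = tibble::as_tibble(clinical),
              clinical_noise_sd = clinical_noise_sd,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$dim) != 3 || any(cfg$dim < 8))
    stopf("grid must be 3D with at least 8 voxels per axis")
  if (cfg$n_control < 2 || cfg$n_pd < 2)
    stopf("both groups need at least 2 subjects")
  if (any(cfg$regions$radius <= 0)) stopf("region radii must be > 0")
  if (abs(cfg$loading_control) > 1 || abs(cfg$loading_pd) > 1)
    stopf("covariance loadings must lie in [-1, 1]")
  if (cfg$noise_sd < 0 || cfg$clinical_noise_sd < 0)
    stopf("noise standard deviations must be >= 0")
  if (cfg$age_range[2] <= cfg$age_range[1]) stopf("degenerate age range")
  if (any(abs(cfg$clinical$target_r) >= 1))
    stopf("requested clinical |correlation| must be < 1")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config> %s grid @ %gmm, %d controls + %d pd, sigma=%gmm\n",
    "  atrophy %.0f%%, slopes %g/%g GM/yr, loadings %g/%g, seed %d\n"),
    paste(x$dim, collapse = "x"), x$voxel_mm, x$n_control, x$n_pd,
    x$smooth_sigma_mm, 100 * x$atrophy_frac, x$slope_control, x$slope_pd,
    x$loading_control, x$loading_pd, x$seed))
  invisible(x)
}

region_masks <- function(cfg) {
  purrr::map(seq_len(nrow(cfg$regions)), function(i) {
    r <- cfg$regions[i, ]
    sphere_mask_array(cfg$dim, c(r$cx, r$cy, r$cz), r$radius)
  }) |> stats::setNames(cfg$regions$name)
}

roles_mask <- function(cfg, masks, role) {
  sel <- cfg$regions$role == role
  if (!any(sel)) return(array(FALSE, cfg$dim))
  Reduce(`|`, masks[sel])
}

#' Generate a synthetic grey-matter cohort
#'
#' Each subject's volume is built as baseline minus group atrophy (inside the
#' atrophy region), minus the group age slope times centred age (inside the
#' age region), plus the group loading times a subject latent factor (inside
#' seed and network regions), plus voxel noise; the result is Gaussian
#' smoothed and clipped at zero — mirroring the segment, modulate, smooth
#' order of VBM preprocessing.  Clinical scores are generated from the
#' (noiseless) subject seed signal via [generate_clinical_scores()].
#'
#' @param config a [synth_config()].
#' @param dir if non-NULL, write per-subject NIfTI volumes, the subject CSV
#'   manifest, the mask, a sphere-labelled atlas and the truth record (JSON)
#'   into this directory.
#' @return list of class `synthetic_cohort` with elements `cohort`
#'   (a [gm_cohort()]), `subjects`, `clinical` (long per-visit score table),
#'   `truth` (every planted parameter plus region masks), and `paths` when
#'   written to disk.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_control + cfg$n_pd
  group <- rep(c("control", "pd"), c(cfg$n_control, cfg$n_pd))
  pd <- as.integer(group == "pd")
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$prop_male, "M", "F")
  latent <- stats::rnorm(n)
  scan_date <- as.Date("2015-01-01") + sample.int(700, n, replace = TRUE)

  affine <- default_affine(cfg$dim, cfg$voxel_mm)
  masks <- region_masks(cfg)
  brain <- sphere_mask_array(cfg$dim, (cfg$dim + 1) / 2, cfg$brain_radius)
  atrophy_m <- roles_mask(cfg, masks, "atrophy")
  seed_m <- roles_mask(cfg, masks, "seed")
  network_m <- roles_mask(cfg, masks, "covariance_network")
  age_m <- roles_mask(cfg, masks, "age_slope")
  cov_m <- seed_m | network_m

  mask <- brain_mask(brain, affine)
  voxel_idx <- which(brain)
  base_vol <- cfg$baseline * brain
  slope <- ifelse(pd == 1, cfg$slope_pd, cfg$slope_control)
  loading <- ifelse(pd == 1, cfg$loading_pd, cfg$loading_control)

  values <- matrix(0, n, length(voxel_idx))
  for (i in seq_len(n)) {
    vol <- base_vol -
      (pd[i] * cfg$atrophy_frac * cfg$baseline) * atrophy_m +
      (slope[i] * (age[i] - cfg$age_ref)) * age_m +
      (loading[i] * cfg$latent_scale * latent[i]) * cov_m
    vol <- vol + array(stats::rnorm(prod(cfg$dim), sd = cfg$noise_sd), cfg$dim)
    vol <- smooth_volume(vol, cfg$smooth_sigma_mm, cfg$voxel_mm)
    vol[vol < 0] <- 0
    values[i, ] <- vol[voxel_idx]
  }

  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group, age = age, sex = sex, scan_date = scan_date,
    medicated = ifelse(pd == 1, stats::runif(n) < 0.31, FALSE))

  # clinical scores ride on the measured seed-region GM, so the planted
  # marginal correlation is recoverable from the ROI means downstream
  seed_cols <- match(which(seed_m & brain), voxel_idx)
  seed_signal <- if (any(!is.na(seed_cols))) {
    rowMeans(values[, seed_cols[!is.na(seed_cols)], drop = FALSE])
  } else rep(0, n)
  clinical <- generate_clinical_scores(seed_signal, cfg, subjects)

  truth <- list(
    config = cfg, affine = affine,
    region_masks = masks, brain_mask = brain,
    atrophy_mask = atrophy_m, seed_mask = seed_m,
    network_mask = network_m, age_mask = age_m,
    age = age, group = group, latent = latent, seed_signal = seed_signal,
    atrophy_effect = cfg$atrophy_frac * cfg$baseline,
    slopes = c(control = cfg$slope_control, pd = cfg$slope_pd),
    loadings = c(control = cfg$loading_control, pd = cfg$loading_pd))

  out <- structure(list(cohort = gm_cohort(values, mask, subjects),
                        subjects = subjects, clinical = clinical,
                        truth = truth),
                   class = "synthetic_cohort")
  if (!is.null(dir)) out$paths <- write_synthetic_cohort(out, dir)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$cohort)
  cat(sprintf("  clinical: %d score values over %d visits\n",
              sum(!is.na(x$clinical$value)), length(unique(x$clinical$visit))))
  invisible(x)
}

#' Generate per-visit clinical scores tied to seed grey matter
#'
#' Each score is `alpha + beta * seedGM + gamma * age + noise`, with `beta`
#' chosen so that the marginal correlation with the seed signal equals the
#' configured target in population.  Two visits per subject are produced
#' (one before and one after the scan date) with visit-level noise and
#' missingness, so nearest-visit matching has realistic structure.
#'
#' @param seed_values per-subject seed grey-matter signal.
#' @param config a [synth_config()] (uses `clinical`, `clinical_noise_sd`,
#'   `missing_rate`).
#' @param subjects subject table with `subject_id`, `age`, `scan_date`.
#' @return long tibble: `subject_id`, `visit`, `visit_date`, `score`, `value`.
#' @export
generate_clinical_scores <- function(seed_values, config, subjects) {
  stopifnot(all(is.finite(seed_values)))
  cfg <- config
  if (any(abs(cfg$clinical$target_r) >= 1))
    stopf("requested clinical |correlation| must be < 1")
  n <- length(seed_values)
  z <- if (stats::sd(seed_values) > 0) {
    (seed_values - mean(seed_values)) / stats::sd(seed_values)
  } else rep(0, n)
  visit_offsets <- list(`1` = -45L, `2` = 20L)
  rows <- purrr::map(seq_len(nrow(cfg$clinical)), function(j) {
    sc <- cfg$clinical[j, ]
    r <- sc$target_r
    core <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    base <- sc$mean + sc$sd * core + sc$age_coef * (subjects$age - mean(subjects$age))
    purrr::map(names(visit_offsets), function(v) {
      val <- base + stats::rnorm(n, sd = cfg$clinical_noise_sd * sc$sd)
      val[stats::runif(n) < cfg$missing_rate] <- NA_real_
      tibble::tibble(subject_id = subjects$subject_id,
                     visit = as.integer(v),
                     visit_date = subjects$scan_date + visit_offsets[[v]],
                     score = sc$score, value = val)
    }) |> dplyr::bind_rows()
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id, .data$score, .data$visit)
}

#' Simulate seed and network ROI means from the latent-factor model
#'
#' The ROI-granularity counterpart of [generate_cohort()]'s covariance
#' structure: within each group, seed and network region means share a
#' standard-normal latent factor scaled by the group loading, plus
#' independent region-level noise.  Useful for fast power and size studies
#' of the interaction test.
#'
#' @param n_control,n_pd group sizes.
#' @param loading_control,loading_pd latent loadings in \[-1, 1\].
#' @param noise_sd region-mean noise sd relative to a unit latent factor.
#' @param seed RNG seed (optional).
#' @return tibble with `group`, `seed_gm`, `network_gm`.
#' @export
simulate_covariance_rois <- function(n_control, n_pd,
                                     loading_control = 0.6, loading_pd = 0,
                                     noise_sd = 0.4, seed = NULL) {
  if (abs(loading_control) > 1 || abs(loading_pd) > 1)
    stopf("loadings must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_control + n_pd
  lam <- rep(c(loading_control, loading_pd), c(n_control, n_pd))
  z <- stats::rnorm(n)
  tibble::tibble(
    group = rep(c("control", "pd"), c(n_control, n_pd)),
    seed_gm = lam * z + stats::rnorm(n, sd = noise_sd),
    network_gm = lam * z + stats::rnorm(n, sd = noise_sd))
}

write_synthetic_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- x$truth$config
  affine <- x$truth$affine
  mask <- x$cohort$mask
  voxel_idx <- x$cohort$voxel_idx
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, showWarnings = FALSE)
  paths <- character(nrow(x$subjects))
  for (i in seq_len(nrow(x$subjects))) {
    arr <- array(0, cfg$dim)
    arr[voxel_idx] <- x$cohort$values[i, ]
    paths[i] <- file.path(vol_dir, paste0(x$subjects$subject_id[i], ".nii.gz"))
    write_nifti_array(arr, affine, paths[i])
  }
  manifest <- dplyr::bind_cols(tibble::tibble(path = paths), x$subjects)
  manifest_path <- file.path(dir, "subjects.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  clinical_path <- file.path(dir, "clinical.csv")
  utils::write.csv(x$clinical, clinical_path, row.names = FALSE)
  mask_path <- file.path(dir, "mask.nii.gz")
  write_mask(mask, mask_path)

  # sphere-labelled atlas over the planted regions
  lab <- array(0L, cfg$dim)
  for (i in seq_len(nrow(cfg$regions)))
    lab[x$truth$region_masks[[i]] & lab == 0L] <- i
  atlas_vol_path <- file.path(dir, "atlas.nii.gz")
  write_nifti_array(lab, affine, atlas_vol_path)
  atlas_csv_path <- file.path(dir, "atlas_lookup.csv")
  utils::write.csv(data.frame(id = seq_len(nrow(cfg$regions)),
                              name = cfg$regions$name),
                   atlas_csv_path, row.names = FALSE)

  truth_path <- file.path(dir, "truth.json")
  truth_small <- list(
    seed = cfg$seed, n_control = cfg$n_control, n_pd = cfg$n_pd,
    atrophy_frac = cfg$atrophy_frac, baseline = cfg$baseline,
    slope_control = cfg$slope_control, slope_pd = cfg$slope_pd,
    loading_control = cfg$loading_control, loading_pd = cfg$loading_pd,
    latent_scale = cfg$latent_scale, noise_sd = cfg$noise_sd,
    smooth_sigma_mm = cfg$smooth_sigma_mm,
    regions = as.data.frame(cfg$regions),
    atrophy_voxels = which(x$truth$atrophy_mask),
    age_voxels = which(x$truth$age_mask))
  jsonlite::write_json(truth_small, truth_path, auto_unbox = TRUE, digits = NA)

  list(dir = dir, manifest = manifest_path, clinical = clinical_path,
       mask = mask_path, atlas_volume = atlas_vol_path,
       atlas_lookup = atlas_csv_path, truth = truth_path, volumes = paths)
}

#' Atlas object for a synthetic cohort's planted regions
#' @param x a `synthetic_cohort`.
#' @export
synthetic_atlas <- function(x) {
  stopifnot(inherits(x, "synthetic_cohort"))
  cfg <- x$truth$config
  lab <- array(0L, cfg$dim)
  for (i in seq_len(nrow(cfg$regions)))
    lab[x$truth$region_masks[[i]] & lab == 0L] <- i
  atlas_labels(lab, x$truth$affine,
               data.frame(id = seq_len(nrow(cfg$regions)),
                          name = cfg$regions$name))
}
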