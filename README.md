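# vbmtools

Voxel-based morphometry (VBM), structural covariance and cross-sectional
brain-ageing analysis of grey-matter density maps, for neuroimaging groups
comparing a patient cohort against controls — motivated by early
Parkinson's disease, where the questions are focal grey-matter loss
(amygdala), altered seed-based structural covariance, accelerated
age-related decline, and the link between regional grey matter and
non-motor clinical scores.

The package consumes what a VBM preprocessing chain produces — modulated,
smoothed grey-matter partial-volume NIfTI volumes in a common template
space, plus a subject/clinical table — and provides the inference stages:

* **Group comparison.** Voxel-wise GLM with age/sex covariates and
  permutation **cluster-extent FWE** correction: threshold the deficit
  t-map at a predefined cutoff (default *t* > 4), refer each cluster's
  size to the permutation null of the maximal cluster size, corrected
  *p* = (1 + #{null ≥ size})/(B + 1), exact enumeration when the design
  admits it. Plus the conventional uncorrected check (*t* > 2.8,
  *p* < 0.005 two-tailed) and MDS-UPDRS III severity splitting at 21.
* **Structural covariance.** Seed-based Pearson r maps per group,
  balanced random subsampling of the larger group (100 repeats, averaged),
  and the group-interaction regression

  *Y* = *a* + *b·X* + *c·*PD + *d·*PD*·X* + *e*

  with per-group z-scoring, where *b* reads as the control-group
  correlation and *t_d* tests the group difference in covariance.
* **Brain ageing.** Per-group voxel-wise age slopes (GM-units/year),
  thresholded slope-difference maps (default 0.002/year, 20-voxel
  clusters, 26-connectivity), the same interaction model with X = age for
  significance (BH-FDR, optionally small-volume), and ROI slope tables.
* **Clinical association.** Nearest-visit score matching (ties → earlier
  visit; backward fill of missing values; provenance recorded), Pearson
  correlation and age/sex-adjusted regression.
* **Synthetic cohorts.** A reproducible generator that plants focal
  atrophy, group-specific age slopes, a seed-anchored covariance network
  and correlated clinical scores into smoothed grey-matter phantoms, with
  a truth record for scoring recovery — so the whole pipeline can be
  validated without access-controlled clinical data.

Results are tibbles; fitted objects have broom-style `tidy()`/`glance()`
methods and ggplot2 `autoplot()` methods; everything chains with the pipe.

## Worked example

```r
library(vbmtools)

cfg <- synth_config(n_control = 40, n_pd = 80, seed = 1)   # 8% planted atrophy
syn <- generate_cohort(cfg)
syn$cohort
#> <gm_cohort> 120 subjects (control=40, pd=80) x 9328 in-mask voxels on a 32x32x32 grid

design <- build_design_matrix(syn$cohort$subjects, c("age", "sex"))
fwe <- permutation_cluster_fwe(syn$cohort, design, cluster_forming_t = 4,
                               n_perm = 999, alpha = 0.05,
                               atlas = synthetic_atlas(syn), seed = 2)
tidy(fwe)
#> # A tibble: 2 x 9
#>   cluster_id  size peak_stat peak_x peak_y peak_z peak_label p_corrected significant
#> 1          1   102      6.59     12     -4    -10 amygdala_R       0.001 TRUE
#> 2          2     1      4.23      6     18     14 unlabelled       0.137 FALSE
```

The 102-voxel cluster is the planted "amygdala" atrophy: its peak t of 6.6
sits inside the planted sphere (the atlas labels the peak), and its
corrected p of 0.001 is the smallest value 999 permutations can report —
no permuted relabeling produced a cluster that large. The singleton voxel
elsewhere is noise and is correctly non-significant.

```r
roi <- brain_mask(syn$truth$age_mask, syn$truth$affine)
roi_slope_comparison(syn$cohort, list(hippocampus_R = roi))
#>          region slope_control slope_pd slope_difference   t_d    p_d n_voxels
#> 1 hippocampus_R     -0.000953 -0.00318          0.00222 -2.33 0.0217      515
```

The ROI table recovers the planted age-decline difference: patients lose
grey matter in this region about 0.0022 GM-units/year faster than controls
(the planted rates were −0.001234 vs −0.004434 before smoothing
attenuation), and the interaction test flags the difference at p ≈ 0.02.

The full pipeline (simulate → VBM → covariance → ageing → clinical) runs
from one config:

```r
cfg <- pipeline_config(input = "synthetic", out_dir = "results/run1",
                       master_seed = 7)
report <- run_pipeline(cfg)          # writes maps, tables and report.json
```

or from the shell via `inst/scripts/run-pipeline.R --config pipeline.yaml`.

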