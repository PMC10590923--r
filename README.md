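# noemri

Analysis of nuclear Overhauser enhancement (NOE) MRI Z-spectra for
single-slice preclinical brain studies, in R.

Saturation-transfer MRI sweeps a saturation pulse across frequency offsets
and records the attenuated water signal — the Z-spectrum
`Z(w) = S(w)/S0`. Superimposed on direct water saturation (DS) and
semi-solid magnetization transfer (MT) sit the relayed nuclear Overhauser
effect (rNOE, ~ -3.5 ppm; sensitive to mobile lipid and protein protons)
and the amide (+3.5 ppm) and amine (+2 ppm) exchange pools. Comparing these
signals between wild-type (WT) and Alzheimer's-model (AD) mouse cohorts
region by region is a candidate route to early markers of macromolecular
change. `noemri` implements the full analysis chain for that design:

* **Phantom generation** — synthetic single-slice WT/AD cohorts with an
  8-ROI label layout, voxelwise five-pool Lorentzian spectra, a smooth
  polynomial B0 field, a low-power WASSR stack, and ground truths anchored
  to reported group means (`phantom_config()`, `simulate_cohort()`).
* **Preprocessing** — per-voxel B0 estimation from the WASSR spectral
  minimum (cubic spline, 0.001 ppm search grid) and spectrum re-gridding
  (`estimate_b0_map()`, `apply_b0_correction()`); spatio-spectral SVD
  denoising of the Casorati matrix with a median singular-value criterion
  (`svd_denoise()`).
* **Contrasts** — `NOE_MTR(%) = 100 (S_ref - S_-3.5)/S_ref` maps,
  MTR-asymmetry curves, and voxelwise five-pool fitting
  `Z(w) = 1 - sum_n a_n s_n^2 / (s_n^2 + 4(w - w_n)^2)` by bounded
  Levenberg-Marquardt least squares, with per-pool amplitude maps and
  attenuation decomposition (`compute_noe_mtr()`, `compute_mtr_asym()`,
  `fit_multipool()`, `decompose_at_offset()`).
* **Registration** — fuzzy c-means skull stripping, histogram matching,
  multiscale mutual-information affine alignment, diffeomorphic demons
  refinement, nearest-neighbour label transfer (`skull_strip_fcm()`,
  `multiscale_affine()`, `demons_refine()`, `transfer_labels()`).
* **Statistics** — ROI means into a tidy cohort table; linear mixed-effects
  group test (`value ~ group + (1 | roi)`, REML), intraclass correlation
  from the variance components, and per-ROI OLS (equal-variance t-test)
  with significance flags (`fit_lmm()`, `compute_icc()`, `per_roi_ols()`,
  `stats_report()`), plus `tidy()`/`glance()` methods and
  `autoplot()`/`plot_cohort()` figures.
* **Pipeline** — `run_pipeline()` sequences the whole analysis from a YAML
  or in-code config and writes NIfTI maps, CSV tables, JSON reports and a
  run manifest; `inst/exec/noemri` is a thin command-line wrapper
  (`simulate`, `b0correct`, `denoise`, `mtr`, `fit`, `register`, `stats`,
  `run-all`).

## Worked example

Simulate a small cohort (64 px slices, 5 + 5 subjects), map NOE_MTR with B0
correction, and test the group difference per region:

```r
library(noemri)
library(dplyr)

cfg    <- phantom_config(size = 64, n_per_group = 5, seed = 1)
cohort <- simulate_cohort(cfg)

tab <- bind_rows(lapply(cohort$subjects, function(s) {
  b0  <- estimate_b0_map(s$wassr, s$zspec$mask)
  mtr <- compute_noe_mtr(apply_b0_correction(s$zspec, b0))
  roi_means(mtr, s$labels, "noe_mtr", s$subject_id, s$group)
}))

stats_report(tab, "noe_mtr")
#> == noe_mtr ==
#> Mixed model group effect: -1.710 (SE 0.111), p = 2.186e-53
#> ICC (ROI): 0.900
#>   cerebral_cortex       -0.85  p = 2.075e-10 **
#>   cerebral_peduncle     -0.82  p = 1.107e-05 **
#>   corpus_callosum       -1.16  p = 1.599e-08 **
#>   entorhinal_cortex     -2.21  p = 5.637e-11 **
#>   fimbria               -3.28  p = 6.052e-10 **
#>   hippocampus           -2.99  p = 4.2e-13 **
#>   hypothalamus          -1.18  p = 1.02e-06 **
#>   thalamus              -1.19  p = 5.006e-09 **
```

The group effect is the AD-minus-WT shift in NOE_MTR percentage points: AD
subjects sit ~1.7 points lower on average across regions, the hippocampus
and fimbria drop the most (~3 points, matching their configured ground
truths), and the ICC of 0.9 says most residual variance is between regions
rather than within. `plot_cohort(tab)` draws the per-region group point
plot, and `autoplot()` works on contrast maps, B0 maps and asymmetry
curves.

For the full pipeline (denoised five-pool fitting, pool amplitude maps,
optional atlas registration, reports and manifest):

```r
res <- run_pipeline(run_config(phantom = cfg, fit_rois = "hippocampus"),
                    out_dir = "noemri_out")
```

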