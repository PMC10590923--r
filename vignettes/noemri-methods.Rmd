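---
title: "Models and methods behind noemri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind noemri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noemri)
```

## The measurement and the model

Saturation-transfer MRI attenuates the water signal by irradiating at a
frequency offset $\omega$ (ppm, water = 0) before readout. Sweeping $\omega$
yields the Z-spectrum $Z(\omega) = S(\omega)/S_0$, whose structure carries
contributions from direct water saturation (DS), semi-solid magnetization
transfer (MT), the relayed nuclear Overhauser effect (rNOE, upfield around
$-3.5$ ppm, sensitive to mobile lipid/protein protons), and the amide
($+3.5$ ppm) and amine ($+2$ ppm) exchange pools.

`noemri` models the Z-spectrum at the lineshape level, as a sum of five
Lorentzians:

$$Z(\omega) = 1 - \sum_{n=1}^{5} \frac{a_n\,\sigma_n^2}
  {\sigma_n^2 + 4(\omega - \omega_n)^2},$$

where $a_n$ is the peak amplitude (fraction of the reference signal),
$\omega_n$ the pool centre and $\sigma_n$ the full width at half maximum, so
that $L_n(\omega_n) = a_n$ and $L_n(\omega_n \pm \sigma_n/2) = a_n/2$.
This is the standard amplitude/FWHM parameterization; a form in which
$\sigma_n$ enters the denominator linearly and the squared offset is
subtracted is dimensionally inconsistent, can become negative or singular,
and contradicts the meaning of $\sigma_n$ as a FWHM, so it is not used.

Two scalar contrasts sit on top of the model:

* **NOE_MTR** $= 100\,(S_{\mathrm{ref}} - S_{-3.5})/S_{\mathrm{ref}}$, with
  $S_{\mathrm{ref}}$ the unsaturated ($\pm 300$ ppm) acquisition averaged
  over its two polarities. It mixes DS, MT and rNOE but needs only two
  images.
* **MTR$_{asym}$** $(\Delta\omega) = (S(+\Delta\omega) -
  S(-\Delta\omega))/S_{\mathrm{ref}}$, reported against the negative offset
  so an rNOE-dominated asymmetry plots positive.

The five-pool fit (`fit_multipool()`) separates the overlapping pools: each
voxel's normalized spectrum is fitted by bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`, analytic Jacobian, at most 200 iterations,
tolerance $10^{-8}$), every voxel starting from the same initial values, so
results are independent of voxel ordering and of the number of forked
workers. Defaults (`default_pool_config()`): DS at $0 \pm 0.3$ ppm
($a_0 = 0.8$, $\sigma_0 = 2$, $\sigma \in [0.5, 10]$); MT at $-2.5 \pm 2$
ppm ($\sigma_0 = 25$, $\sigma \in [10, 100]$ — the broad pool); NOE at
$-3.5 \pm 0.5$ ($\sigma_0 = 3$); amide at $+3.5 \pm 0.5$; amine at
$+2.0 \pm 0.5$. The amine centre is a configuration choice (some protocols
prefer $+2.75$ ppm); edit the config tibble to change it. Amplitudes are
bounded to $[0, 1]$. Voxels that fail to converge are flagged and carry the
initial values, keeping maps NaN-free.

`decompose_at_offset()` converts fitted pools into percentage contributions
$100\,L_n(\omega)/\sum_m L_m(\omega)$, which sum to 100 wherever the total
attenuation is non-zero.

## Preprocessing

**B0 correction.** The static field varies across the slice, shifting each
voxel's spectrum by $b_0(x, y)$ ppm. A low-power WASSR acquisition samples
only the narrow DS line over $\pm 1$ ppm in 0.1 ppm steps; a natural cubic
spline through each voxel's WASSR spectrum is minimized on a 0.001 ppm grid
and the argmin is the shift estimate (`estimate_b0_map()`). Minima at the
window edge or flat spectra are flagged invalid rather than raised.
`apply_b0_correction()` then re-grids each measured spectrum onto the
nominal offsets by evaluating it at $\omega + b_0$: cubic spline inside the
densely sampled $|\omega| \le 6$ ppm region, linear interpolation beyond,
queries clamped to the acquired range. The interpolation dialect is fixed so
runs are bit-reproducible. A nominal acquisition reads 0–1 ppm at 0.1 ppm
steps; we acquire both polarities, giving 21 offsets — one-sided sampling
cannot bracket negative shifts.

**Denoising.** Before fitting (and only before fitting — NOE_MTR uses
B0-corrected, un-denoised data), masked voxel spectra are stacked into a
Casorati matrix (voxels × offsets) and filtered by truncated SVD
(`svd_denoise()`). Components are retained when their singular value
exceeds `multiplier × median(singular values)`; the multiplier defaults to
2 and is exposed because median-criterion variants differ in this constant.
Singular values at float-noise level are first zeroed so exactly low-rank
inputs report their true rank.

## The synthetic phantom

No public data accompany the in-vivo study design this package supports, so
the `phantom` module generates the study conditions: single 128×128 slices,
a 173-offset schedule (0–6 ppm at 0.1, 6–10 at 0.5, 10–20 at 1, 20–100 at
10 ppm, mirrored about water; protocols of this design often quote 174
offsets, but enumerating these segments gives 173 after endpoint
de-duplication), WASSR stacks, an unsaturated reference, and WT/AD cohorts
of five subjects each.

Ground truths (`default_roi_params()`) anchor the four regions with
in-vivo group means from this study design — hippocampus (NOE_MTR 40.1/37.1%, rNOE 15.4/12.9%,
amide 10.2/8.8%, amine 8.0/7.4%), entorhinal cortex (37.0/34.8%),
hypothalamus (40.8/39.6%), fimbria (40.7/37.3%) — and give the remaining
regions plausible values with the same AD-lower direction. The MT amplitude
is fixed at 0.06 (consistent with a ~6% MT contribution at $-3.5$ ppm in
the whole-brain decomposition); the DS width is 4 ppm, chosen so that DS can
supply its ~52% share of the attenuation at $-3.5$ ppm with amplitude
below 1 (a 2 ppm DS line cannot); the DS amplitude itself is solved per
region by `calibrate_noe_mtr()` so the noiseless NOE_MTR equals the target
exactly (closure to $10^{-6}$).

Noise is additive Gaussian on the normalized signal (default sd 0.01);
magnitude-image Rician behaviour is out of scope at this SNR. The B0 field
is a low-order 2D polynomial (default peak ≈ 0.15 ppm, well inside the
WASSR window), optionally scaled per subject by a uniform draw
(`b0_scale_range`). The WASSR acquisition is simulated as a lone narrowed
DS pool (amplitude 0.85, FWHM 0.6 ppm), reflecting its low saturation
power. Ground truth is a per-region constant within each group: subject
variability comes only from noise (and field jitter when enabled), so
cohort ground-truth means equal the configured values exactly. The phantom
therefore validates *parameter recovery under the stated noise model*; it
does not emulate anatomy, partial-volume mixing, B1 inhomogeneity, motion
or exchange-rate physics (the model is lineshape-level, not
Bloch–McConnell), so passing tests bound algorithmic error, not biological
generality.

`b0_sensitivity_config()` packages one deliberately constructed cohort: a
purely lateral quadratic field (peak 0.45 ppm) with per-subject amplitude
jitter $U(0.1, 1)$ and a small (0.25%) entorhinal group separation. Lateral
regions acquire subject-varying NOE_MTR bias when uncorrected, masking the
entorhinal effect, while central regions (hippocampus, hypothalamus) are
nearly untouched — the qualitative pattern in which B0 correction changes
one region's significance path and leaves others alone. The fixture was
constructed to exhibit exactly this pattern.

The whole-brain decomposition fixture (`pool_set_from_decomposition()`)
solves pool amplitudes by root bracketing so the noiseless contributions at
$-3.5$ ppm are DS 52 / MT 6 / NOE 40 / amide 1 / amine 1 percent at a total
attenuation of 0.40. Its "noisy acquisition" is the mean of 4096
independent noisy voxel realizations (`simulate_average_spectrum()`),
matching how a whole-brain average spectrum is formed from a noisy image.

## Registration

The atlas stand-in is the phantom's noiseless anatomical image plus labels
(`phantom_atlas()`); real-atlas slice selection is out of scope. The
pipeline mirrors the usual template workflow:

1. `skull_strip_fcm()` — 3-class fuzzy c-means on intensities; brain = the
   union of the two brightest-centroid classes at membership > 0.5 (which
   classes constitute "brain" is not canonical; two-brightest is our
   documented choice), then largest connected component and morphological
   closing (disc radius 2). Degenerate histograms fall back to Otsu.
2. `histogram_normalize()` — monotone quantile mapping onto the fixed
   image, 256 landmarks.
3. `multiscale_affine()` — ten rounds; both images blurred with a geometric
   sigma schedule 4.0 → 0.4 px (the schedule shape is our choice; only
   "reduced" is prescribed by convention), an incremental affine estimated
   per round by Nelder–Mead maximization of 32-bin mutual information
   (MI tolerates residual intensity mismatch after histogram matching;
   derivative-free search avoids MI gradient estimation on small slices).
   Rounds that do not improve the round's own metric are discarded.
4. `demons_refine()` — 50 demons iterations appending a dense displacement
   field; the update force is fluid-smoothed, composed through the
   exponential map (scaling-and-squaring; the diffeomorphic variant is the
   default to avoid folding, plain additive Thirion updates are available),
   and the field elastic-smoothed with $\sigma = 1$ px. Folding in > 1% of
   pixels warns.
5. `transfer_labels()` — nearest-neighbour resampling throughout, so the
   output label set is a subset of the input's (no interpolated labels).

## Statistics

ROI means feed a long cohort table. `fit_lmm()` fits
`value ~ group + (1 | roi)` by REML (lme4) — disease group as the fixed
effect, a random intercept per region (no slope structure is assumed) —
and reports a Wald normal-approximation p for the group effect; singular
random-effect fits are reported, not raised. The ICC is defined from the
fitted variance components, $\sigma^2_{roi}/(\sigma^2_{roi} +
\sigma^2_{res})$. `per_roi_ols()` regresses each region's means on the
group indicator — algebraically the equal-variance two-sample t-test — and
flags regions at $\alpha = 0.05$ with `*`/`**` markers. Per-region p-values
are reported uncorrected, matching the per-region reporting convention; a
Holm adjustment is available but off by default.

## Numerical choices and problem sizes

* Offsets are rounded to $10^{-6}$ ppm before de-duplication so segment
  endpoints shared between float-generated sequences collapse.
* The fit treats `info` codes 1–3 from `nls.lm` as convergence.
* Registration tests run at 96 px and the mixed-model simulations at 100
  replicates; the end-to-end recovery suite runs the full 128 px, n = 5 per
  group cohorts at default noise, and the voxelwise fit in that suite is
  evaluated over the hippocampus ROI, whose mean is the quantity under
  test — fitting the rest of the slice would change runtime, not the value.
* Seeds: every stochastic step draws from a seed derived deterministically
  from the configuration seed (WT cohort base seed, AD base seed + 1,
  subject seeds `base*1000 + i`), so whole runs are reproducible
  byte-for-byte.

## Known limitations

* The phantom shares one lineshape family with the fitting model, so fit
  recovery is an internal-consistency check; real spectra contain
  super-Lorentzian MT wings and exchange-rate dependence the model ignores.
* NOE_MTR inherits DS and MT contamination by construction; only the
  five-pool fit separates them, and only up to the identifiability allowed
  by the offset schedule and noise.
* The mixed model treats regions as exchangeable random draws, which eight
  named regions only approximate.
* B1 correction, motion, drift, 3D acquisitions and DICOM/Bruker ingestion
  are out of scope.
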