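---
title: "Denoising and connectivity analysis of spinal-cord resting-state fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising and connectivity analysis of spinal-cord resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spinecorr` implements a slice-wise analysis chain for resting-state fMRI
of the cervical spinal cord — nuisance regression driven by principal
components of non-neural tissue, physiological (RETROICOR) correction,
weighted in-plane motion correction, zero-phase band-pass filtering,
sub-region ROI extraction, autocorrelation-corrected Fisher-z
connectivity and exact nonparametric group inference — together with a
synthetic phantom that makes every stage falsifiable. This vignette
documents the model each stage assumes, the tunable parameters and their
defaults, what the phantom does and does not emulate, and the numerical
choices that are not forced by the method itself.

# The processing model

The chain treats each axial slice independently (the cord moves and
pulsates differently at each vertebral level, and the acquisition is
effectively 2-D in time). Per slice:

1. **Weighting kernel.** An anisotropic 2-D Gaussian centred on the cord
   (gray + white matter centroid), with the per-axis FWHM set at the
   bounding extent of the CSF mask. It concentrates the motion cost
   function on the cord and its high-contrast CSF rim.
2. **Not-spine mask and PCA regression.** Everything outside the dilated
   spine region (dilation radius 3 voxels, a margin against
   partial-volume bleed) is "not spine". The leading principal
   components of these voxels capture structured noise that affects neck
   and cord alike — swallowing events, breathing-linked intensity
   changes — and are regressed from *every* voxel in the slice.
   Components are kept up to 80% cumulative variance, or until two
   successive normalised eigenvalues differ by less than 0.02.
3. **Motion correction (two passes, one interpolation).** The target
   volume is the one closest (least squares) to the voxelwise median
   image. Per-volume in-plane translation is estimated by minimising the
   kernel-weighted sum of squared differences — an exhaustive integer
   search via FFT cross-correlation, a free quadratic sub-voxel seed
   from the 3×3 SSD neighbourhood, then coordinate-wise parabolic
   refinement of the continuous band-limited objective. The estimates
   are median-filtered (5 points, nearest-replicated edges) and the
   filtered trace is applied to the *uncorrected* series with a single
   Fourier (sinc-family) resampling, so the data are interpolated once.
   Rotations and through-plane motion are excluded by design.
4. **RETROICOR.** Cardiac phase advances linearly between detected pulse
   peaks; respiratory phase uses amplitude-histogram equalisation signed
   by the derivative of the bellows trace. Order-2 Fourier expansions of
   both phases (8 regressors), evaluated at each slice's acquisition
   times, are regressed from all voxels.
5. **CSF PCA regression.** Principal components of the CSF voxels (cap
   50% cumulative variance, same gap rule) are regressed from the cord
   (gray + white) voxels. CSF pulsation is the dominant structured noise
   source shared between CSF and cord tissue.
6. **White-matter eigenvector regression.** The first time-course
   eigenvector of the white-matter voxels — the "global" white-matter
   signal — is regressed from all gray and white voxels. Variants used
   for sensitivity analysis: a combined white+gray mask, or a slightly
   eroded white-matter mask (`pipeline_config(regressors = ...)`).
7. **Band-pass.** Chebyshev Type II, passband 0.01–0.08 Hz (variants
   0.01–0.07 and 0.01–0.13), applied forward–backward for exactly zero
   phase.
8. **Sub-regions.** Gray and white matter are split into left/right
   ventral/dorsal quadrants through the cord centroid; gray-matter
   voxels within 2 voxels of the midline (the central gray commissure)
   belong to no quadrant. Each of the 8 masks is eroded by a discrete
   Euclidean disk — radius 3 voxels for gray matter, 11 for white — with
   the radius decremented until the mask is non-empty.

All regressions are per-voxel ordinary least squares with an intercept;
residuals keep their voxel mean and are exactly orthogonal to the
design. No polynomial detrending is applied — the band-pass removes
drift, and a detrend would be redundant with it.

## Connectivity and inference

Pearson correlations (between a seed voxel and cord voxels, or between
eroded-ROI mean series) become z scores via `z = atanh(r)·sqrt(dof−3)`
with an effective-degrees-of-freedom correction for temporal
autocorrelation. Two corrections are implemented behind one function.
The classical lag-1 Bartlett form `dof = N(1 − r1a·r1b)/(1 + r1a·r1b)`
is exact for AR(1) noise but badly under-corrects band-passed series,
whose autocorrelation extends over many lags: on 0.01–0.08 Hz-filtered
noise at TR 3.6 s it leaves the null z overdispersed by ~25–40%. The
default is therefore the all-lag Bartlett variance sum,
`dof = N / (1 + 2·Σ_k w_k·ra(k)·rb(k))`, with sample autocorrelations to
lag N/3 under a triangular taper — the two coincide for AR(1) noise, and
only the all-lag form achieves the correction's purpose (a standard
normal null) on band-limited data. Two further adjustments complete the
calibration. The data-driven estimate is scaled by `(1 − p/N)` for the
`p` nuisance regressors already projected out (typically ~15 per slice:
not-spine components, 8 RETROICOR columns, CSF components, the
white-matter eigenvector and the intercept) — the GLM dof cost of the
design. And it is capped at [filter_dof()], the effective sample size a
white-noise series retains after the band-pass
(`trace(C)²/trace(C²)` for the filter covariance `C`, about 72 of 150
volumes for the default band): sample autocorrelations of short
band-limited series are leakage-biased toward white, so the data-driven
estimate systematically overshoots what the filter can admit. Without
these corrections the null z variance is inflated by roughly 25–45%.
`|r|` is clamped at `1 − 1e−7` so degenerate ROIs give large finite
scores; `dof` is clamped to `[4, N]`.

Seed maps use |z| > 3.29 (two-tailed 99.9%) and a minimum cluster extent
of 9 contiguous voxels; contiguity is face-only 6-connectivity in 3-D
(configurable to in-plane 8-connectivity) — the single-voxel display
variant uses a one-tailed p < 0.001 threshold with no cluster rule.
Group inference: per ROI pair, the median z across a subject's 12 slices,
then an exact two-sided Wilcoxon signed-rank test across the 22 subjects
(full distribution of the positive-rank sum with midranks for ties;
normal approximation with tie and continuity corrections above n = 25),
Bonferroni-corrected over the 28 pairs at the 0.05 and 0.01 tiers.
Box-whisker summaries use type-7 (linear-interpolation) quartiles and
1.5 IQR whiskers; the quartile convention matters for small n and is
stated here because plotting software defaults differ.

# The phantom

`phantom_config()` defines one simulated acquisition. Defaults emulate a
7 T cervical protocol: twelve 4-mm axial slices, 150 volumes at a volume
acquisition time of 3.6 s, a 64×64 in-plane window at the interpolated
0.31 mm resolution. Geometry is parametric: four half-ellipse gray-matter
horns joined by a central commissural band inside a white-matter ellipse,
a CSF annulus, a dark partial-volume gap, and neck tissue out to the
window edge. An analytic geometry (rather than a drawn one) makes the
subdivision and erosion stages exactly testable.

**Planted signals.** Band-limited series are synthesized as sums of
random-phase sinusoids on the DFT bins inside the signal band, so their
power is confined to the band by construction. For a pair with planted
`rho > 0` the shared and independent components are
Gram–Schmidt-orthonormalised before mixing
(`sqrt(rho)·shared + sqrt(1−rho)·independent`), so the *sample*
correlation of the noiseless horn signals equals the planted value to
machine precision — parameter-recovery tests become sharp checks rather
than statistical ones. Pairs with `rho = 0` are left as independent
draws: their sample correlations sit at chance level, as independent
signals should, which is what the null-calibration checks require. Note
that "chance level" for band-limited series means the Fisher null at an
effective dof of twice the number of in-band bins, not at the number of
volumes. Defaults: `rho_vv = 0.5` between ventral horns, `rho_dd = 0.35`
between dorsal horns, zero elsewhere.

**Confounds.** Each tissue couples to: a pulse-like cardiac waveform
(von Mises bump, κ = 3, ~1.05 Hz) and a respiratory waveform (~0.3 Hz
with a weak second harmonic), both evaluated at the slice acquisition
times (and therefore aliased, as they are in TR ≈ 3.6 s data); a slow
CSF-driven pulsatility mode (strongest in CSF, weaker in cord tissue); a
second CSF-confined mode; a global cord fluctuation dominant in white
matter; two neck-only slow components; multiplicative bulk "swallow"
events (Poisson rate 3 per run, 1–2 volumes, 3% amplitude) affecting all
tissue; slow sinusoidal in-plane drift (0.3 voxels) with sporadic
single-volume jumps; and white thermal noise (σ = 25) everywhere.

Three structural choices deserve comment. First, the *dominant*
pulsatile modes (the CSF mode and the global cord fluctuation) couple
with a spatially uniform gain: they model single coherent physical
sources, and coherence is precisely what makes one eigenvector an
adequate nuisance regressor — the situation the pipeline's regression
stages assume. Second, the quasi-periodic confounds and the neck modes
couple with heterogeneous per-voxel gains (mean 1, sd `gain_cv` = 1),
which is what lets a PCA separate them into distinct components. Third,
the second CSF mode couples with zero-mean, sign-alternating gains — a
flow mode spatially orthogonal to the bulk pulsation. This is not
cosmetic: if its gain pattern overlapped the uniform dominant mode, the
leading CSF principal component would be a blend of the two time
courses, and regressing that blend from cord voxels would *inject* the
second mode into tissue that never contained it. Second, the confound amplitudes
were fixed, before any inference tests were run, to reproduce the
operating point reported for real data of this kind: median gray-matter
TSNR in the low 30s before CSF/WM regression rising by roughly 25–30%
after it,
and typical component counts of 3–5 (not-spine) and 2–6 (CSF) under the
80%/50% cumulative-variance rules. The cardiac κ = 3 keeps the waveform
peaked enough for reliable peak detection while limiting harmonics above
order 2 — which RETROICOR cannot remove and which alias into the signal
band — to a few percent of cardiac variance.

**What the phantom does not emulate:** MR physics (k-space sampling,
T2* blurring, SENSE reconstruction noise correlations, fat shift),
through-plane motion and rotation, non-stationary heart/breathing rates,
spatially smooth coil-sensitivity structure in the thermal noise, and
real anatomical variability between subjects and slices. Tests passing
on the phantom therefore validate the *algorithmic* chain — that each
stage removes what it models and that the statistics are calibrated —
not robustness to every artifact of real acquisitions.

# Numerical choices

- **Filter design.** The passband edges are the stated 0.01–0.08 Hz; the
  order (5 analogue poles, i.e. a 10th-order band-pass) and 30 dB
  stopband attenuation are not dictated by the method and were chosen
  for stability at 150 samples; stopband edges sit at 0.5× the low edge
  and 1.25× the high edge. Forward–backward application uses
  odd-reflection padding of 10× the filter length. The result has no
  group delay (the cross-correlation of a filtered sinusoid with its
  input peaks at lag 0), but strict time-reversal symmetry holds only up
  to the IIR edge transient: the poles at the 0.005 Hz stopband edge
  decay over ~100 samples, leaving ~1% asymmetry near the series ends.
  Because the zero-phase filter is linear, its action is precomputed
  once as an n×n operator and applied to whole slices as a matrix
  product. Series are demeaned before filtering (DC belongs to the
  stopband anyway).
- **Eigenvalue gap rule.** "Successive eigenvalues differing by less
  than 2%" is read as an absolute difference of total-variance-normalised
  eigenvalues below 0.02, since the neighbouring percentages in the same
  rule refer to cumulative variance fractions; a relative variant
  (`gap_rule = "relative"`) is provided. Voxel series are demeaned but
  not variance-normalised before PCA.
- **Erosion.** The discrete disk is `{(i,j): i² + j² ≤ r²}`; pixels
  beyond the image border count as background. Erosion is computed via
  an exact squared Euclidean distance transform, so the radius fallback
  is a threshold sweep rather than repeated morphology; a brute-force
  disk-fitting oracle checks it exhaustively on small masks.
- **Translation estimation.** The integer search is exhaustive over
  ±8 voxels using FFT correlation identities; sub-voxel refinement runs
  on the exact weighted-SSD objective under Fourier interpolation.
  Accuracy on noiseless shifts is ~1e−3 voxels with one refinement
  sweep (the pipeline default) and ~2e−4 with two (the function
  default); the documented contract is 0.1.
- **Ties.** Target-volume selection and the integer translation search
  break exact ties toward the lowest index; midranks handle ties in the
  signed-rank test.
- **Degenerate inputs.** Empty masks raise errors naming the offending
  region; all-zero group cells report p = 1; constant voxels are
  excluded from TSNR medians; flat images cannot be registered.
- **Problem sizes.** Unit tests run on reduced phantoms (32–48 voxel
  grids, 1–2 slices, 40–100 volumes) chosen so each check still
  exercises the full code path; the acceptance checks use the full
  64×64×12×150 default for the 22-subject group study, 2004 slices for
  the null calibration and 10,000 AR(1) pairs for the z calibration.

# Design decisions that were genuinely open

- **Affine registration.** The functional-to-anatomical affine stage of
  scanner pipelines is tool- and scanner-specific. A simplified
  slice-wise affine (translation, bounded per-axis scaling of 1%/5%,
  bounded 5% shear, Hellinger dependence cost on the joint histogram) is
  provided but disabled by default: the phantom is generated already in
  anatomical space, and recovery of known distortions — not equality
  with any external tool — is the supported contract.
- **Null-study motion.** The null calibration disables planted motion
  and its correction: translation handling is validated separately, and
  the calibration question — is the z chain standard normal when nothing
  is planted? — is about the correlation statistics, not resampling.
  (Measured with motion enabled, residual translation times the image
  gradient adds a small shared gray-matter component and pushes a few
  pairs' exceedance above the nominal band.)
- **Motion absorbed by regression.** With sub-voxel drifts the
  motion-induced intensity change is nearly linear
  (translation × gradient), and the slice-wide drift time course appears
  in the not-spine principal components — so the regression stage, which
  runs before motion estimation as the processing order dictates,
  removes most of the apparent motion before the estimator sees it. The
  explicit translation estimates on the default phantom are therefore
  close to zero even though motion was planted; what the pipeline
  guarantees, and what is tested, is that no recoverable motion remains
  in its output. With larger (super-voxel) displacements the linear
  approximation fails and the estimator does the work instead.
- **Registration histograms.** The optional affine stage samples both
  images with bilinear interpolation on a grid shifted by an irrational
  sub-voxel offset, so no candidate transform is ever grid-aligned;
  otherwise the joint-histogram cost dips spuriously at integer
  alignments, where one image escapes interpolation smoothing.
- **Scopes.** Not-spine regressors clean every voxel in the slice; CSF
  regressors clean cord voxels; the white-matter eigenvector cleans gray
  and white voxels. White-matter quadrants do not exclude a central
  band (only the gray commissure is ambiguous anatomically).
- **Edge handling.** The 5-point median filter replicates edge values;
  the filter's reflection padding and the FFT's periodic boundary are
  documented rather than configurable.

# Known limitations

Even with the all-lag dof correction, the band-limit cap and the
regression dof accounting, the slice-level null z is not perfectly
calibrated pair by pair: gray-matter pairs (signal-dominated under the
null) run a few percent hot and carry a small positive bias (~0.1 z)
from imperfect removal of shared CSF-driven fluctuations, while
white-matter pairs inherit a small negative bias from the
global-eigenvector regression. The null-calibration checks bound the
resulting exceedance of z > 1.65 to a few points around the nominal
5%. Global-signal
style regression (the white-matter eigenvector) induces weak negative
correlations among white-matter sub-regions — visible in group results
as negative white-matter pairs — which is a property of the method, not
a bug, and motivates the regressor-permutation variants. Slice
independence ignores any true rostro-caudal continuity of cord signals;
inter-slice seed maps are supported, but group inference is within-slice
only.
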