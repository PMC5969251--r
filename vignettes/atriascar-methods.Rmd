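---
title: "Atrial scar segmentation from LGE MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrial scar segmentation from LGE MRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriascar)
```

# The problem

Atrial fibrosis — native or created by ablation therapy — retains
gadolinium contrast and appears hyperintense on late gadolinium-enhanced
(LGE) cardiac MRI, while healthy, nulled myocardium stays dark.
Quantifying scar in the *left atrial* wall is much harder than in the
ventricle: the wall is only about 3 mm thick, image quality is degraded by
motion and contrast wash-out, and bright structures adjacent to the wall
(aortic wall, valves, artifacts) mimic enhancement. `atriascar` implements
a fully automatic pipeline for this problem:

1. **Multi-atlas whole-heart segmentation (MA-WHS)** of a non-contrast
   anatomical ("Roadmap") volume: every atlas is registered to the target
   by a hierarchical scheme (global affine, per-substructure local affine,
   B-spline deformable), scored by spatially encoded mutual information;
   the warped atlas labels are combined by multiscale patch-based label
   fusion.
2. **Anatomy mapping**: the whole-heart segmentation is carried onto the
   LGE grid using the scanner geometry (voxel-to-world affines) refined by
   affine and deformable registration.
3. **Wall and blood pool**: the atrial wall is the 3 mm morphological
   dilation shell of the endocardial LA+PV segmentation; the blood pool is
   its 5 mm erosion; LGE intensities are z-normalised by blood-pool mean
   and SD.
4. **Scar classification**: each slice is oversegmented into SLIC
   super-pixels (grid interval S = 4 px); super-pixels overlapping the
   wall by at least 20% are described by 16 intensity features, reduced by
   mRMR (mutual-information quotient) selection, and classified
   enhanced/non-enhanced by an RBF-SVM tuned by grid-search
   cross-validation. The union of enhanced super-pixels is the scar mask;
   fibrosis extent is reported as scar volume over wall volume.

Clinical LGE data and consortium atlases cannot ship with the package, so
a synthetic phantom generator reproduces the statistical structure the
pipeline depends on, and every stage is validated against analytic oracles
and generator ground truth.

# Similarity model for registration

The spatially encoded mutual information (SEMI) of a target $I$ and a
warped atlas $A$ accumulates one joint histogram per spatial subregion
$s$,

$$H_s(i, j) = \sum_{x \in \Omega} w_1(I(x))\, w_2(A(x))\, W_s(x),$$

where $w_1, w_2$ are Parzen window contributions (box assignment by
default, a truncated Gaussian optionally) and $W_s$ is a spatial weight.
The similarity is the sum over subregions of the Shannon mutual
information of each normalised $H_s$. With a single subregion and uniform
weights this reduces *exactly* to standard MI — the property the unit
tests pin down against an independently coded MI and brute-force pair
counting.

Choices the contract leaves open, and what this package does:

* **Spatial weights** $W_s$: Gaussians centred on a near-balanced regular
  grid of subregion centres (default $n_s = 8$, i.e. $2 \times 2 \times
  2$), bandwidth one quarter of the mean volume extent. Any smooth
  partition-like weighting satisfies the contract; user-supplied weight
  matrices are accepted for testing and experimentation.
* **Binning**: images are linearly rescaled to the bin range over the
  overlap region; 64 bins by default, reduced at coarse pyramid levels
  where few voxels are available.
* **MI base**: $\log_2$ (bits). The optimiser is invariant to the base.

# Registration stages

* **Global affine.** Nelder–Mead over a staged parameterisation
  (translation, then rotation + log-scale, then optional shear) on a
  3-level multiresolution pyramid (factors 4, 2, 1), maximising SEMI.
  Nelder–Mead never returns a worse point than its start, and a final
  guard falls back to the identity if the optimum scores materially (more
  than 2%) below it. The band exists because sampling at fractional
  coordinates smooths intensities and costs the true optimum a sliver of
  MI relative to the integer-aligned identity; a strict comparison would
  discard correct recoveries.
* **Local affine.** One translation + scale transform per labelled
  substructure, scored by MI over the structure's dilated bounding box.
  The per-structure affines are blended into a continuous displacement by
  normalised Gaussian weights centred at the structure centroids (sigma =
  half the bounding-box extent, with a small uniform floor so the
  displacement is defined everywhere, decaying to zero far from all
  structures). Structures under 100 voxels are skipped with a warning and
  inherit the global transform.
* **Deformable.** Cubic B-spline free-form deformation, control spacing 10
  voxels, bending-energy weight 0.01. The control-point update direction
  is the analytic intensity-difference force (residual times warped-image
  gradient, projected onto the control grid by the B-spline basis) with a
  backtracking step search on the SSD; a gradient-free search over the
  roughly $10^3$ control parameters would not converge in reasonable
  time, which is why the dense stage departs from the gradient-free
  optimiser used for the affine stages. SEMI remains the reported
  similarity: it is traced across outer iterations, the best-scoring state
  is kept, and a drop beyond the divergence tolerance stops the stage
  early.

Known-transform recovery on structured phantoms (translation (5,3,0)
voxels within 1 voxel, isotropic 1.1 scale within 2%, a smooth 2-voxel
sinusoidal field with mean residual under 1 voxel) is part of the test
suite. Note the recovered transforms map *target* points into the *atlas*,
so the recovered dense field approximates the negated forward warp.

# Label fusion

Per voxel $x$, each atlas $a$ votes for its label with weight $w_a(x)$ and
the fused label is $\arg\max_l \sum_a w_a(x)\,\delta(L_a(x), l)$, ties
broken toward the lowest label id. The methods differ only in $w_a$:

* **MV**: uniform weights (majority vote).
* **LWV**: a Gaussian of the local mean squared intensity difference over
  the patch, bandwidth the target's intensity SD.
* **PF**: the patch-wise conditional probability $p(i_x \mid j_x)$, with
  joint and marginal probabilities estimated by box-Parzen histograms
  accumulated over the patch around $x$ (radius 2, i.e. $5^3$ patches;
  32 bins).
* **MSP**: the PF similarity summed over a Gaussian scale space (sigmas 0,
  1, 2 voxels), so a small patch carries both fine structure and coarser
  context — useful where the LA blood pool is locally indistinguishable
  from other chambers.

Two contract ambiguities are resolved as follows and are invariant to the
voxel-wise argmax: the multiscale similarity *sums* over scales (an
average would rescale all weights equally), and per-voxel weights are not
normalised across atlases (normalisation cancels in the argmax). The
multiresolution shortcut (computing coarse scales on downsampled grids) is
implemented as plain full-resolution smoothing here; at the package's
problem sizes the exact computation is affordable and avoids documenting
an approximation.

On seeded synthetic atlas cohorts the mean LA Dice of MSP exceeds both
single-scale PF and plain majority voting (asserted as a property test),
mirroring the clinical finding that multiscale patch fusion is the
strongest of the non-joint fusion schemes. Single-scale PF alone is a
statistical tie with majority voting under these conditions: conditional
probabilities estimated from $5^3$-voxel patches over a $32 \times 32$
histogram are sparse, and the multiscale sum is what stabilises them —
a finding worth knowing before using PF on its own.

# SLIC super-pixels

Per-slice local k-means in the joint feature space
$D = \sqrt{d_c^2 + (d_s/S)^2 m^2}$ with grid interval $S = 4$ px and a
$2S \times 2S$ search window. The energy reported per iteration is
$\sum_x D^2$, i.e. the k-means objective in the scaled feature space;
because the previous assignment always remains a candidate and centre
updates are means, this energy is non-increasing — the property the tests
assert. Two standard details are flag-controlled: perturbing initial
centres to the lowest-gradient $3\times3$ neighbour (off by default; on a
constant image it uselessly shifts the grid) and connectivity enforcement
(on by default; orphan fragments merge into the dominant touching
super-pixel).

The compactness weight $m$ is in intensity units. The reference
calibration procedure is visual boundary adherence; here $m = 4$ (for
blood-pool-normalised intensities) was fixed once by measuring, on
phantoms, the Dice ceiling of the super-pixel partition against the
generator's scar boundary — the same criterion, made quantitative. At the
default 0.75 mm in-plane spacing, $S = 4$ px spans 3 mm, matching the
assumed LA wall thickness (the often-quoted 2.8 × 2.8 mm² equivalence is
inconsistent with that spacing; the pixel value is authoritative).

# Training-set construction and features

Clicks (simulated by the generator; interactive in clinical use) select
enhanced super-pixels; a click only counts once per super-pixel. The wall
mask is the 3 mm dilation shell of the endocardial LA+PV segmentation
(per-axis structuring radius `round(mm / spacing)`, minimum 1 voxel, so
anisotropic grids get ellipsoidal elements); the blood pool is the 5 mm
erosion. The overlap rule — enhanced if clicked and overlapping the wall
by ≥ 20% of the super-pixel's own area, non-enhanced if unclicked and
overlapping, excluded otherwise — is evaluated in 2D on the super-pixel's
slice, the natural reading since super-pixels are per-slice objects.
Super-pixels with fewer than 4 pixels are excluded (the features below
need at least 4 samples).

The 16 intensity features use these conventions (the source material does
not fix them): population SD and variance; Fisher skewness and excess
kurtosis, both 0 for constant input; the 3rd central moment for "central
moments"; mode as the most frequent of 32 histogram bins (ties to the
lowest centre); linear-interpolation quantiles for the IQR; Shannon
entropy in bits over 32 bins; coefficient of variance defined as 0 when
the mean is 0.

mRMR feature selection uses the mutual-information quotient: the first
feature maximises MI(feature; label); later picks maximise relevance over
mean redundancy with the already-selected set. Features are discretised
into 8 equal-frequency bins; the redundancy denominator is floored at
1e-12 so constant features (MI 0) cannot blow up the quotient. Selection
is deterministic given the binning, with ties resolved by canonical
feature order. The clinical reference outcome (minimum, mean, SD selected)
is documented but not asserted on synthetic data, where the informative
features depend on the generator.

The SVM uses an RBF kernel with features standardised to training
mean/SD, balanced class weights (wall super-pixels are overwhelmingly
non-enhanced), and (C, γ) chosen by 5-fold cross-validated accuracy over
the classical grid C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} in powers of 4. Folds
are seeded; ties in the grid resolve to the first point, so training is
deterministic per seed.

# Evaluation

Overlap metrics follow the standard definitions (Dice, Jaccard, precision,
NPV with total-voxel term); empty-mask corner cases return flagged
conventions rather than silent numbers (both-empty: Dice/Jaccard 1;
empty prediction: precision NaN). Surface metrics use 6-connectivity
boundary voxel centres in mm; the Hausdorff distance is the exact max-min
(no percentile variant). The classifier report carries accuracy,
sensitivity, specificity, BER = ((1−sens)+(1−spec))/2, and AUC by
trapezoidal integration of the ROC; pooled-over-folds AUC is the default
reading of "average AUC" (per-fold averaging is available from the
per-case reports). The Wilcoxon rank-sum wrapper uses the exact two-sided
distribution for small tie-free samples and the corrected normal
approximation otherwise. The n-SD baselines threshold blood-pool-
normalised intensities, i.e. the reference tissue is the blood pool — the
same normalisation the classifier sees; k-means and fuzzy c-means
partition wall intensities into two clusters with scar the higher-mean
cluster (fuzzy membership > 0.5).

# The phantom generator: what it emulates, and what it does not

Defaults define the package's study conditions; each is a modelling
choice, stated once:

* **Grid** 80 × 80 × 24 voxels at 0.75 × 0.75 × 2 mm — the reconstructed
  resolution of the target application, so S = 4 px super-pixels span
  about one wall thickness. Problem sizes in the tests and acceptance
  script (5-case cohorts, 10 replicates; 48³–64³ registration phantoms)
  were chosen to exercise the methods at these conditions on a single
  CPU.
* **Geometry**: LA as an ellipsoid (radii 13 × 11 × 9 mm) with three
  tubular PV stubs, plus offset ellipsoids/tubes for LV, RV, RA, aorta and
  pulmonary artery — topologically adequate and analytically
  constructible, *not* anatomically realistic meshes.
* **LGE contrast**: blood pool 120 ± 15; healthy wall 100 ± 25
  (incompletely nulled and heterogeneous — about 1.3 blood-SD below the
  blood mean, which is the regime in which 2/4/6-SD thresholding is
  meaningful at all); background 30. Scar is drawn at
  blood mean + 4 SD with wash-out heterogeneity 0.5: each contiguous patch
  (2 by default, grown from random directions to exactly the configured
  20% wall fraction) is enhanced at the full offset in its core, falling
  to half at its rim. Three confounding enhancement foci (0.65 × the scar
  offset) sit just outside the wall, emulating aortic-wall/valve/artifact
  enhancement — the dominant false-positive source for intensity-only
  methods.
* **Degradations**: in-plane Gaussian PSF of 0.5 px (partial volume
  across the thin wall), Gaussian acquisition noise SD 8 (Rician
  optional), optional low-order multiplicative bias field (off by
  default), and, for atlases, smooth sinusoidal displacement fields with
  amplitude 3 mm and wavelengths of the order of the field of view
  (amplitude well below half the minimum wavelength, hence invertible).
* **Clicks**: a configurable fraction (default all) of scar-overlapping
  super-pixels receive one click on a scar voxel — "relatively dense"
  expert clicking, without click misplacement.

What passing tests on these phantoms shows: the pipeline's machinery is
correct (oracle equivalences), recovers known transforms and known scar
under its own assumptions, and beats intensity-only baselines when the
image exhibits the stated confounds. What it does not show: performance
on real LGE MRI, where enhancement statistics, anatomy, motion artifacts
and observer behaviour are far richer than the generator. Clinically
reported performance for this class of pipeline on AF patient cohorts
(whole-heart Dice around 89%, scar Dice 79 ± 5%, accuracy 88%, AUC 0.91,
pre/post-ablation fibrosis extent 26.9 ± 11.2% vs 32.8 ± 6.4%) is quoted
here only as context and is not reproducible from synthetic data.

Two further scope notes. The phantom cohorts used for end-to-end
classifier validation take the generator's ground-truth anatomy as the
mapped whole-heart segmentation (a perfect MA-WHS); registration accuracy
is validated separately by the known-transform recovery suite, and the
label-fusion comparison uses the generator's deformed atlases directly,
their residual deformation standing in for registration error. The human
manual-correction step of clinical ground-truth construction is replaced
by the generator's exact scar mask.

# Numerical details and degenerate inputs

* Resampling fills out-of-grid samples with background (0); label maps
  and masks always use nearest-neighbour interpolation, so labels are
  never invented.
* Separable convolutions renormalise the kernel over in-bounds taps, so
  constant images are preserved exactly at boundaries.
* The patch conditional probability returns 0 when the marginal
  $p(j_x)$ is zero; fusion tie-breaks are deterministic (lowest label
  id).
* Histogram binning uses half-open equal-width bins with the maximum
  clamped into the last bin; integer-valued images with range below the
  bin count therefore bin injectively, which several oracle tests rely
  on.
* Erosion that empties a mask raises an error advising a smaller radius;
  a zero blood-pool SD, single-class training tables, empty atlas lists
  and out-of-grid clicks all raise explicit errors.
* All stochastic components (phantoms, fold assignment, clustering
  restarts) take explicit seeds; reruns with the same configuration and
  seed are bit-identical.

# Known limitations

* The SEMI spatial weighting follows the Eq.-contract (any smooth
  weighting), not any specific published variant; results are not
  sensitive to $n_s$ on phantoms, but this was not tuned broadly.
* The deformable stage optimises SSD forces, appropriate for
  same-modality registration (Roadmap-to-Roadmap atlases, self-mapping
  Roadmap-to-LGE refinement on phantoms); strongly multi-modal pairs
  would need an MI-gradient force model.
* Joint label fusion and graph-cut-refined baselines are out of scope, as
  is DICOM parsing (NIfTI-1 with voxel-to-world affines stands in for
  scanner geometry).
* The generator does not simulate k-space acquisition, navigators or
  motion; Rician noise and bias fields are available but simplistic.
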