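# atriascar

Fully automatic segmentation and quantification of left atrial (LA) scar
in late gadolinium-enhanced (LGE) cardiac MRI, for researchers working on
atrial fibrillation imaging who need an end-to-end, testable
implementation of the multi-atlas + super-pixel classification approach —
without access to clinical data.

Scar retains gadolinium and appears hyperintense in LGE MRI while healthy
nulled myocardium stays dark; quantifying it in the ~3 mm atrial wall
drives patient selection and assessment of ablation therapy. The pipeline:

1. **Multi-atlas whole-heart segmentation** of an anatomical "Roadmap"
   volume. Each atlas `(A_a, L_a)` is warped to the target `I` by
   hierarchical registration (global affine → per-substructure local
   affines → B-spline free-form deformation) maximising **spatially
   encoded mutual information**: per spatial subregion `s`, a weighted
   Parzen joint histogram `H_s(i,j) = Σ_x w1(I(x)) w2(A(x)) W_s(x)` and
   the similarity `Σ_s MI(H_s)`.
2. **Label fusion**: the consensus label at `x` is
   `argmax_l Σ_a w_a(x) δ(L'_a(x), l)`. Weights: uniform (MV), Gaussian
   of the local mean squared difference (LWV), the patch conditional
   probability `p(i_x | j_x)` (PF), or that similarity summed over a
   Gaussian scale space (MSP, the default).
3. **Anatomy mapping** to the LGE grid via the volume affines, refined by
   affine + deformable registration.
4. **Wall and blood pool**: wall = 3 mm dilation shell of the endocardial
   LA+PV mask; blood pool = 5 mm erosion; intensities z-normalised by
   blood-pool mean/SD.
5. **Scar classification**: per-slice SLIC super-pixels
   (`D = sqrt(d_c² + (d_s/S)² m²)`, S = 4 px), 16 intensity features per
   wall-overlapping super-pixel (overlap ≥ 20%), mRMR (MI-quotient)
   feature selection, RBF-SVM with grid-search CV; scar mask = union of
   enhanced super-pixels; fibrosis extent percentage (FEP) = scar / wall
   volume.
6. **Evaluation**: Dice/Jaccard/precision/NPV, Hausdorff/ASD, accuracy,
   sensitivity, specificity, BER, ROC/AUC, Wilcoxon rank-sum,
   Bland–Altman, and the conventional baselines (fixed threshold, 2/4/6
   blood-pool SDs, k-means, fuzzy c-means).

A synthetic cardiac phantom generator (ellipsoidal chambers, thin atrial
wall, scar with contrast wash-out, confounding enhancement, noise/PSF,
deformed atlas sets, simulated expert clicks) makes the whole pipeline
runnable and testable; see the methods vignette
(`vignettes/atriascar-methods.Rmd`) for the model and every default.

## Worked example

```r
library(atriascar)

# one synthetic patient: anatomy + LGE with known scar
cfg <- phantomConfig(seed = 7)
heart <- makeHeartPhantom(cfg)
lge <- makeLGEPhantom(heart$labels, cfg)

# anatomy-derived masks and normalisation
endo <- BinaryMask(imgData(heart$labels) == 1L, spacing = cfg$spacing)
wall <- extractWall(endo, 3)
bp <- extractBloodPool(endo, 5)
nrm <- normalizeIntensities(lge$volume, bp)

# super-pixels, simulated clicks, training table
sp <- oversegmentVolume(nrm, S = 4, m = 4)
clicks <- makeClicks(lge$scar, sp, density = 1, seed = 7)
tab <- buildTrainingSet(sp, clicksToSuperpixels(clicks, sp), wall, nrm)

# train, predict, assemble, score
model <- trainSvm(tab, mrmrSelect(tab, 3), seed = 7)
pred <- predictScar(model, tab)
scar <- assembleScarMask(sp, pred, wall)
unlist(overlapMetrics(lge$scar, scar)[c("dice", "jaccard", "precision")])
#>      dice   jaccard precision
#> 0.8061395 0.6752376 0.6930579
fibrosisExtent(scar, wall)   # percent of wall volume
#> [1] 24.87642
fibrosisExtent(lge$scar, wall)  # generator truth: 20% of the wall
#> [1] 19.99681
```

A Dice of 0.81 against the voxel-exact generator truth and a fibrosis
extent of 24.9% against the true 20% — super-pixel granularity, wash-out
rims and confounding enhancement account for the disagreement.
Cross-validated cohort experiments
(`makePhantomCase` + `scarLooExperiment`, or `runExperimentSuite`) are
the honest versions of this number.

A thin CLI over the same functions lives at `inst/cli/atriascar.R`
(subcommands `simulate`, `register`, `fuse`, `superpixels`, `evaluate`,
`run`, `suite`).

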