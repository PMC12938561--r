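# glioseg

Unsupervised multi-class glioma segmentation from multi-modal MRI, for
researchers who need tumor delineations (whole tumor, tumor core, enhancing
tumor) without any annotated training data — e.g. for cohorts lacking expert
labels, for semi-automatic annotation bootstrapping, or for longitudinal
volumetry.

The method is a two-stage pipeline over co-registered, skull-stripped NIfTI
volumes (T1, T1ce, T2, FLAIR; T2 optional):

**Stage 1 — whole-tumor mask (FLAIR only).** Percentile normalization to
[0, 1] using p2/p98 over brain voxels, then per-slice Sauvola adaptive
thresholding

    T(x, y) = m(x, y) · (1 + k·(s(x, y)/R − 1)),   w = 15, k = 0.5, R = 0.5,

with m, s the local window mean and standard deviation, followed by
small-object removal (|C| > S_min), disk opening/closing, and a strict
voxel-wise fusion across the axial, coronal and sagittal planes
(M = M_ax ∧ M_cor ∧ M_sag; majority/OR/single-plane variants are available
for ablation).

**Stage 2 — subregion labeling.** Voxels inside the mask, described by their
z-scored multi-modal intensity vectors, are clustered patch-wise (5³ patches,
50% overlap) by affinity propagation on the similarity
s(i, k) = −Σ_b |A_i^b − A_k^b| / σ_b, with the median pairwise similarity as
the shared preference and a four-iteration moving-average smoothing of the
responsibility/availability messages in place of damping. Patch exemplars are
re-clustered hierarchically (≤ 3 levels), the best level is chosen by an
intra/inter cluster-validity score, and clusters are mapped to necrosis /
edema / enhancing tumor by ranking their mean intensity profiles (highest
T1ce → enhancing; highest FLAIR/T2 among the rest → edema; lowest → necrosis).
TC = enhancing + necrosis; WT = all three. The stage is fully deterministic.

The package also ships the evaluation metrics (Dice, HD95, recall,
precision), a deterministic multi-modal tumor phantom generator with
ground truth and image-degradation operators (noise, bias field,
downsampling, motion), and ablation/robustness harnesses. See the methods
vignette (`vignettes/methods.Rmd`) for the full model description and design
rationale.

## Worked example

Segment a synthetic case with known ground truth:

```r
library(glioseg)

case   <- generate_phantom(phantom_spec(seed = 42))   # volume + ground truth
labels <- segment_tumor(case$volume)                  # stage 1 + stage 2
labels
#> <label_volume> 64 x 64 x 64 voxels
#> background   necrosis      edema  enhancing
#>     258200         88       3056        800

scores <- evaluate_case(labels, case$labels, spacing = c(1, 1, 1))
scores[, c("region", "dice", "hd95", "recall", "precision")]
#>  region      dice hd95    recall precision
#>      WT 0.9704724    1 0.9426386         1
#>      TC 1.0000000    0 1.0000000         1
#>      ET 1.0000000    0 1.0000000         1
```

Reading the output: the label volume uses internal codes 1 = necrosis,
2 = edema, 3 = enhancing tumor (export with `write_labels(..., dialect =
"brats")` for the BraTS {1, 2, 4} convention). Here the whole-tumor mask
reaches Dice 0.97 against the phantom's ground truth — the missing 6% of
recall is the outermost boundary shell trimmed by the strict three-plane
fusion, at perfect precision — and the interior subregions are recovered
exactly, which is expected on a clean phantom whose class contrasts are
well separated. A 95th-percentile surface distance (`hd95`) of 1 mm means
the mask boundary sits within one voxel of the true boundary.

Real data enter through `read_multimodal()`:

```r
vol <- read_multimodal(c(T1 = "t1.nii.gz", T1ce = "t1ce.nii.gz",
                         T2 = "t2.nii.gz", FLAIR = "flair.nii.gz"))
labels <- segment_tumor(vol)
write_labels(labels, "prediction.nii.gz", dialect = "brats")
```

A thin command-line front end with subcommands `phantom`, `stage1`,
`stage2`, `segment`, `evaluate`, `ablate` and `robustness` is installed at
`inst/cli/glioseg`.

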