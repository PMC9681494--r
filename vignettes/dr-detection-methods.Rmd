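---
title: "Lesion-aware diabetic retinopathy detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware diabetic retinopathy detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetic retinopathy (DR) is a microvascular complication of diabetes that
is detectable in color fundus photographs through three characteristic
lesion types: microaneurysms (MA, tiny dark dots — the earliest sign),
exudates (EX, bright lipid/protein deposits) and hemorrhages (HEM, larger
irregular dark bleeds). drdetect implements a binary DR screen that fuses
two complementary descriptions of an image:

1. **Clinical lesion counts.** One binary segmentation model per lesion
   class is trained on image patches; its probability maps are merged,
   thresholded, and the distinct lesions counted. The three counts
   `(MA, EX, HEM)` form a 3-dimensional, clinically interpretable feature
   block.
2. **Deep texture features.** A "topless" image-classification backbone
   (VGG-16 or ResNet-50 with the fully connected head removed) is used as
   a fixed feature extractor; the terminal convolutional volume
   (7×7×512 or 7×7×2048) is flattened to 25,088 or 100,352 numbers.

The two blocks are concatenated — `[deep ‖ MA ‖ EX ‖ HEM]`, giving 25,091
or 100,355 features — and classified with a gradient-boosted tree ensemble
(XGBoost, library defaults, fixed seed). Because boosted trees are
scale-invariant, the raw integer counts enter unscaled.

## Segmentation model

Each per-lesion model is a U-Net: five encoder blocks of two 3×3 "same"
convolutions (ReLU) with 2×2 max pooling between them, a mirrored decoder
of 2×2 transposed convolutions with skip concatenations, and a 1×1 sigmoid
output head. The patch side `n` must be divisible by 16 (four poolings);
the canonical configuration uses `n = 128` for MA (small lesions) and
`n = 256` for EX/HEM, with filter widths doubling per block from
`base_filters`.

Training minimizes the **binary focal loss**

$$\ell(p, y) = \begin{cases}
 \alpha\,(1-p)^{\gamma}\,(-\log p) & y = 1\\
 (1-\alpha)\,p^{\gamma}\,(-\log(1-p)) & y = 0
\end{cases}$$

averaged over pixels, with the canonical $\gamma = 2$, $\alpha = 0.25$.
The focal down-weighting of easy background pixels addresses the extreme
foreground/background imbalance of lesion masks. Optimization is Adam at
learning rate $10^{-3}$; the loss parameters, rate, batch size (32) and
epochs (3) are all exposed in `seg_config()`.

Two numerical choices matter in practice:

* **Prior-logit output bias.** The output bias is initialized to
  $\operatorname{logit}(\pi)$ with an assumed foreground prior
  $\pi = 0.02$ (`fg_prior`). Without it, the first optimization phase is
  spent collapsing the sigmoid towards the background rate before any
  lesion structure can be learned; with it, the short 3-epoch protocol is
  spent entirely on shape. This is standard practice for heavily
  imbalanced dense prediction heads.
* **Float32 engine.** The convolution engine (Rcpp/Armadillo, im2col +
  BLAS gemm) runs in single precision with hand-written backpropagation;
  gradients are verified against finite differences and against an
  independent double-precision R implementation in the test suite.

### Protocol

Patches are tiled with overlapping anchors (default stride `n/2`; a final
anchor is snapped to the image edge rather than padding, so no pixels are
invented). Each training patch is augmented with probability 0.5 by a
random horizontal/vertical flip plus a rotation drawn uniformly from the
full circle; the identical transform is applied to the mask (nearest
neighbor, re-binarized at 0.5) and rotated corners are filled by
reflection rather than a constant. K-fold cross-validation (k = 5) is
applied to the patches; steps per epoch equal the number of training
patches divided by the batch size; the fold with the best validation
accuracy is retained. Fold assignment is patch-level by default, with an
image-grouped option (`group =`) to prevent leakage between folds when
several patches come from one photograph.

At inference, patch probability maps are merged by the arithmetic mean of
overlapping predictions (a `max` merge is available), thresholded at 0.5,
and counted.

## Counting lesions

The count operation follows an edge/contour route: Canny edge detection
(Sobel gradients, non-maximum suppression, 50/150 hysteresis on the 8-bit
scale) finds the edges around foreground regions; gaps are closed by a
morphological closing **constrained to the foreground**, so two lesions
separated by background can never be bridged; closed shapes are filled by
a border flood fill and the filled components counted (8-connected).
Consequences of these choices: a lesion with an interior hole counts once
(outer contour), a component cut by the image border still counts, and no
minimum-area filter is applied by default (`min_area` is exposed). On
masks whose components are at least 2 px apart — which the synthetic
generator guarantees — the count provably equals plain connected-component
labeling, and the test suite enforces exact agreement against an
independent labeling oracle on hundreds of generated masks.

## Preprocessing

`enhance()` applies, in order: background zeroing (Otsu threshold on the
grayscale image, largest connected component, 5×5 morphological closing —
parameter-free), green-channel extraction (the highest-contrast channel
for retinal structures), CLAHE on an 8×8 tile grid (clip limit 2 by
default; only the tile size is fixed by the recipe), and gamma correction
`out = 255·(in/255)^γ` with γ = 0.8, i.e. brightening under the plain
reading of the exponent. The disc mask found in the first step is
re-applied at the end so the margins stay exactly zero through the chain.
All steps preserve dimensions and 8-bit semantics (values on the grid
k/255).

## Deep features

Backbones are built layer-by-layer in the same compiled engine: VGG-16
(13 convolutions in five blocks with max pooling, 224×224×3 → 7×7×512)
and ResNet-50 (7×7/2 stem, 3×3/2 max pool, 16 bottleneck blocks with
projection shortcuts, → 7×7×2048). Residual sums are scaled by
$1/\sqrt{2}$ to keep activations well-conditioned through the deep stack.
Inputs are resized bilinearly to 224×224 and normalized with each
architecture's canonical preprocessing (BGR order, ImageNet channel-mean
subtraction), recorded in the feature vector's provenance attributes. The
flattening order is row-major over (row, col, channel) — channel fastest —
and is documented because fused feature indices depend on it.

Pretrained ImageNet weights require a network download, so the package's
testable mode is `weights = "random"`: He-initialized weights drawn from a
seed. Every architectural dimension — and therefore the fused vector
lengths — is identical to the pretrained case; only the feature *content*
differs. Random-weight features carry no class signal, which the ablation
tests exploit: they provide a floor against which the informativeness of
the lesion counts is demonstrated.

## The synthetic data generator

`generate_fundus_image()` emulates the *structure* of annotated fundus
datasets rather than their photographic appearance: a shaded circular eye
disc on black margins; MA as small dark-red dots (radius 2–4 px at the
desk scale), EX as bright yellowish ellipses (4–7 px), HEM as unions of
2–4 overlapping ellipses (one lesion, one connected component; 6–9 px);
Gaussian pixel noise; and one binary mask per class, all-black for healthy
images. Blobs are placed by rejection sampling inside the disc with a
minimum 2 px inter-blob gap (bounded retries, explicit "infeasible
packing" failure), which makes the ground-truth count exactly recoverable
from the mask — the property every counting test relies on. Dataset
generation mirrors the 1:1 healthy/DR class balance of the study design;
DR images draw per-class counts uniformly up to a template maximum
(re-drawn until at least one lesion is present) and receive a severity
grade 0–4 increasing with total lesion load.

What the generator does **not** model: vasculature, the optic disc,
camera vignetting and color variation, lesion texture, or
intensity-calibrated lesion appearance (no public pixel statistics exist
to calibrate against). Passing tests therefore demonstrate that the
pipeline's machinery — patching, training, reconstruction, counting,
fusion — is correct and recovers known ground truth under favorable
contrast; they do not certify clinical performance on real photographs.

## Scaled-down study sizes

All training-dependent checks run on one CPU inside a test suite, so they
use a reduced geometry chosen once: 40 training images (20 healthy /
20 DR) of 96×96 px, 32 px patches tiled at stride 8 (81 patches per
image), `base_filters = 8`, batch 32, 3 epochs, 5 folds — about 240
optimization steps per fold, a few minutes per lesion class. Under these
conditions each class's best cross-validation fold reaches validation
IoU ≥ 0.5 (typically 0.65–0.75). The classifier study uses a 40-train /
20-test split with oracle lesion counts (counted from ground-truth masks
through the package's own counting path), isolating the
classification question from segmentation noise: lesion counts separate
the classes essentially perfectly, while random-weight deep features
perform near chance — the qualitative ordering the ablation harness is
designed to expose.

## Known limitations

* Random-weight backbones cannot reproduce pretrained-feature accuracy on
  real data; they exist for architecture fidelity and ablation floors.
* The U-Net engine is CPU-oriented and float32; it is not intended for
  full-resolution clinical training runs.
* The contour counter is exact for masks with ≥ 2 px component
  separation; lesions that touch (< 2 px apart) may merge into one count,
  as they would for any outer-contour definition.
* Severity grading (0–4) is carried as metadata but not predicted; the
  classifier is strictly binary.
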