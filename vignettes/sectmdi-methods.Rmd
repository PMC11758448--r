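---
title: "Synthetic material decomposition from single-energy CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic material decomposition from single-energy CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectmdi)
```

## The clinical problem

After endovascular thrombectomy, post-interventional cerebral hyperdensities
(PCHD) on noncontrast CT can be either intracranial hemorrhage (ICH) — a
serious complication that changes management — or benign contrast staining
(CS) from retained iodinated agent. The two are nearly indistinguishable on
single-energy CT (SECT) because blood and iodine have similar attenuation at
one tube voltage. Dual-energy CT (DECT) resolves the ambiguity by
three-material decomposition into a virtual noncontrast image (VNC; blood
stays visible) and an iodine overlay map (IOM; iodine stays visible), but
many stroke centers have no DECT scanner.

`sectmdi` implements an image-to-image translation approach to this
problem: a transformer-based generative adversarial network (trans-GAN)
learns the mapping from a SECT volume to the pair of material decomposition
images (sVNC, sIOM), so the established DECT reading rule — blood on the
VNC means hemorrhage, signal confined to the IOM means staining — can be
applied without a DECT acquisition.

## The digital phantom and its forward model

No clinical images ship with the package; a phantom simulator provides
matched (SECT, VNC, IOM) triplets with known ground truth. It implements
the minimal linearized surrogate of three-material decomposition:

$$\mathrm{SECT} = \mathrm{blur}_\sigma(\mathrm{VNC} + k \cdot \mathrm{IOM}) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma_n^2),$$

with the iodine-to-attenuation scale $k$ (default 1), a point-spread blur
(default $\sigma = 0.6$ voxels) and additive noise (default
$\sigma_n = 5$ normalized units). With blur and noise switched off the
identity holds voxel-exactly, which the tests exploit, and ordinary least
squares on lesion voxels recovers $k$.

A case is a near-homogeneous elliptical "brain" (background mean 100,
mild texture SD 3 on the normalized $[0, 256]$ scale, boundary feathered
by $\sigma = 1.2$ voxels — parenchyma on CT is fairly uniform and its
interfaces are not single-voxel steps) carrying 1–2 ellipsoidal lesions of
semi-axes 5–10 voxels. Hemorrhages add intensity drawn from $[40, 90]$ to
the VNC; contrast staining adds $k \cdot$ intensity (drawn from
$[45, 100]$, slightly above the blood range to offset its margin
feathering) through the IOM. The SECT-elevation distributions of the two
classes therefore overlap by construction — across seeds the best
intensity threshold reaches only AUC $\approx 0.6$–$0.7$ — while the
classes are trivially separable on the true decomposition images. This is
the clinical premise in miniature. What distinguishes the classes in SECT
*appearance* rather than mean intensity are two realistic cues: acute
hematomas carry fine-grained, high-contrast internal speckle (SD 45,
correlation length 1.2 voxels — the marked heterogeneity of fresh clot),
whereas contrast staining is homogeneous with feathered margins
($\sigma = 2$ voxels). The speckle is deliberately fine-grained so that
heterogeneity is visible in every small neighbourhood of a hemorrhage:
the routing decision a decomposition network must make is then locally
supported instead of requiring lesion-wide aggregation, which keeps it
learnable at the desk-scale training budget. The case-level label (ICH iff
any lesion deposits blood) is the diagnostic unit.

Default case prevalence is 0.32 ICH-positive, the hemorrhage proportion in
the cohort the method was developed on (61/190 training cases). The
default desk-scale grid is $64 \times 64$ (2D); the full-scale
$256 \times 256 \times 128$ geometry is a configuration choice, and every
component operates on rank-2 or rank-3 volumes.

What the phantom does *not* emulate: skull/bone, reconstruction artifacts,
polyenergetic beam effects, anatomy-dependent lesion priors, and the
spatial statistics of real parenchyma. Passing tests on phantom data
therefore demonstrate that the pipeline learns the intended decomposition
under controlled conditions, not clinical-grade performance.

## Preprocessing

The preprocessing module mirrors standard volumetric practice: resampling
to isotropic 1 mm spacing (trilinear for images, nearest-neighbour for
label masks), center crop/pad to a fixed grid (256×256×128 at full scale),
per-volume min–max normalization to $[0, 256]$, synchronized random
cropping (96³ at full scale) and flip / right-angle rotation augmentation
applied identically to all volumes of a case. Resampling happens before
normalization. Right-angle rotations were chosen over arbitrary angles to
avoid interpolation artifacts at toy scale; the SECT input may be
re-normalized but the VNC/IOM targets stay on the common intensity scale
so the material forward model remains linear across preprocessing.

## The trans-GAN

The generator is a U-shaped windowed-transformer:

* **Encoder** — four blocks: a patch-partition + linear embedding (patch
  size $p$, width $C$), then three blocks of an attention pair followed by
  patch merging, each halving resolution and doubling channels
  ($C, 2C, 4C, 8C$ pyramid).
* **Attention pair** — two successive pre-norm windowed multi-head
  self-attention blocks with residual connections and 4× feed-forward
  (GELU) expansions; the second block's windows are cyclically shifted by
  half a window so information crosses window borders. No relative
  position bias is used at desk scale.
* **Bottleneck** — one attention pair at the deepest resolution followed
  by a patch expansion.
* **Decoders** — two structurally identical, parameter-independent
  branches (sVNC and sIOM) of three cascaded blocks (skip fusion with the
  matching encoder grid, an attention pair, then patch expansion); the
  final block expands by the patch size and projects linearly to one
  channel, restoring the input resolution exactly.
* **Discriminators** — two independent networks (one per target image) of
  four stride-2 convolutions (LeakyReLU 0.2) and a fully connected layer
  producing one realness logit.

Design points that were genuinely open and how they were resolved:

* The bottleneck's attention unit is built exactly like every other
  attention pair (consistency argument).
* Skip connections are included by default and config-switchable; the
  decoder is described as mirroring the encoder, which skip fusion makes
  literal.
* Discriminators are unconditional — they score a (generated or real)
  image alone rather than an (input, image) pair.
* Windows default to 4 at desk scale (7 would suit full scale); windows
  larger than a pyramid level are clamped with a warning.
* Inputs are scaled by $1/256$ at the trunk and predictions by $256$ at
  the head so the network operates on unit-scale activations while the
  loss lives on the normalized intensity scale.

The whole graph is built on a small reverse-mode automatic differentiation
engine written for this package (dense products, batched per-window
attention with an Armadillo kernel, index gathers, layer norm, GELU,
losses), with every operator validated against central finite differences.

## Training

Each iteration draws a batch (default 4) of cases, optionally augmented
and cropped, and updates in turn: each discriminator on (real, detached
fake) pairs, then the generator on

$$L = w_{\mathrm{VNC}} \left( L_1(\hat y_{\mathrm{VNC}}, y_{\mathrm{VNC}}) + L_{adv,1} \right)
    + w_{\mathrm{IOM}} \left( L_1(\hat y_{\mathrm{IOM}}, y_{\mathrm{IOM}}) + L_{adv,2} \right)$$

with non-saturating adversarial terms (a least-squares variant is
selectable). Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
initial learning rate $10^{-3}$) with a plateau scheduler (factor 0.5,
patience 5) evaluated once per completed 50-iteration window on that
window's mean generator objective — evaluating per-window rather than on a
rolling mean keeps "patience 5" meaningful at a few hundred iterations.

The task weights $(w_{\mathrm{VNC}}, w_{\mathrm{IOM}})$ adapt by GradNorm:
with $g_i$ the gradient norm of task loss $i$ on the shared layer (the
last encoder block's patch-merge projection — the deepest representation
shared by both branches), weighted norms $G_i = w_i g_i$ are pulled toward
$\bar G \, r_i^\alpha$, where $r_i$ is the relative training rate
$L_i(t)/L_i(0)$ normalized to mean one (asymmetry $\alpha = 0.5$ — a mild
setting, appropriate for two closely related reconstruction tasks; larger
$\alpha$ forces training rates apart more aggressively). The
weights take their own Adam step (size 0.025) on the gradient of
$\sum_i |G_i - \bar G r_i^\alpha|$ and are renormalized to sum to 2.
Identical tasks provably keep $(1, 1)$, and relabeling the two tasks swaps
the weight trajectory — both are tested.

Three stabilizers make these dynamics well behaved at desk scale, where
batches of 4 phantom cases produce very noisy per-batch losses: (i)
GradNorm engages only after a warmup of one scheduler window, so the
reference losses $L_i(0)$ are recorded after the trivially learned
background offset has decayed and the training-rate ratios compare lesion
learning rather than the initial transient; (ii) the losses and gradient
norms entering the rule are exponentially smoothed (decay 0.9); and (iii) weights are
confined to the trust region $[0.5, 1.5]$ before renormalization so
neither task ever stops training. Without these guards the VNC weight
collapses within a few hundred iterations: the VNC loss starts an order of
magnitude above the IOM loss and falls much faster, and the per-batch
shared-layer gradient norms the rule compares fluctuate over two orders of
magnitude.

Seeds flow from a single integer; a run is replayable bit-for-bit in a
single-threaded session. A non-finite loss aborts with a diagnostic rather
than silently producing NaN weights.

## Image quality and reader statistics

PSNR uses the fixed data range $R = 256$ (the normalization width) so
values are comparable across cases; SSIM uses the standard 11×11 Gaussian
window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$), computed slice-wise
and averaged for volumes, on whole images. Reports aggregate per-case
values as mean ± SD for each target.

The reader-evaluation module reproduces the diagnostic-accuracy toolkit:
sensitivity/specificity/PPV/NPV/accuracy with exact Clopper–Pearson 95%
intervals; the single-operating-point AUC $(\mathrm{sens} +
\mathrm{spec})/2$ with a DeLong placement-value CI; the paired DeLong test
(degenerate variance returns $p = 1$ by convention); unweighted Cohen's
kappa with the large-sample (Fleiss–Cohen–Everitt) standard error; and an
exhaustive reconstruction of 2×2 confusion tables from rounded printed
metrics (half-up, two decimals), which lets published summary rows be
verified back to integer counts. One display subtlety: the
single-operating-point AUC recomputed from two-decimal printed operating
points can land exactly on a half (e.g. $(1.00 + 0.77)/2 = 0.885$), where
display software applies banker's rounding; `auc_from_printed()` therefore
does that arithmetic in exact decimal with half-to-even rounding. For the bundled published operating
points the internal and external generated-image rows reconstruct to
unique tables — (16, 7, 0, 24) and (18, 4, 1, 3) — whose accuracies and
the 0.79 exact lower sensitivity bound re-derive the printed values. The
published external cohort size (6/26 ICH) is inconsistent with the
positive count implied by its printed sensitivity (19 positives); the
reconstruction surfaces this but cannot resolve it.

## Problem sizes and numerical choices

The package's reference experiment (used by `scripts/acceptance.R` and the
acceptance tests) is deliberately desk-scale: 240 phantom cases at 64²,
split 200/40, patch size 2, embedding width 16, batch 4. Training follows
the crop-based protocol of the full-scale method scaled down — random 32²
crops (the analogue of 96³ crops from 256³ volumes) with flip/rotation
augmentation, for a few thousand iterations; at batch 4 this corresponds
to a few dozen epochs over the 200 training cases, which is what "a
training run" means for volumetric translation models that see each volume
through many random crops. Held-out volumes are generated with
sliding-window (tiled) inference at the training crop size, the standard
way to apply a crop-trained network to full volumes: it keeps every
attention window at the grid sizes the weights were trained on.
Evaluation compares the generated sVNC against the copy-input baseline
(PSNR of SECT against VNC) and reads generated images with the
decomposition rule, comparing rank AUCs against the best SECT-intensity
threshold. The continuous case score uses both generated images (VNC
elevation minus mean IOM signal per lesion), as the DECT reading does:
when a partially trained generator splits a lesion's intensity between
the branches, the class information lives in the *ratio* of that split,
which the two-image score captures and a VNC-only threshold would miss.

Other numerical conventions: min–max normalization errors on constant
volumes instead of dividing by zero; GradNorm guards zero initial losses
with an epsilon and clamps weights away from zero before renormalizing;
SSIM's constants stabilize the zero-variance case; confusion-table metrics
with zero denominators are reported as undefined rather than zero; the
Gaussian blur uses replicate edges and is exactly the identity at
$\sigma = 0$.

## Known limitations

* The phantom's texture/margin cues stand in for whatever real SECT
  appearance differences exist between hemorrhage and staining; nothing
  here validates that such cues suffice clinically.
* PSNR/SSIM on synthetic 2D phantoms are not comparable to values reported
  on clinical volumes.
* Kappa and DeLong comparisons of human readers require per-case reader
  calls, which the package can analyse but cannot invent; simulated
  readers exercise the statistics instead.
* The pure-R/Armadillo training loop is single-threaded and desk-scale; it
  is a faithful, testable implementation of the method, not a
  production training system for 256³ clinical volumes.
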