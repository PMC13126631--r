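---
title: "Models and methods behind afmstate"
author: "afmstate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind afmstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-speed atomic force microscopy (HS-AFM) records height maps of single
molecules at video rate, but the images are noisy, laterally blurred by the
finite tip, and distorted by molecular motion between scan lines. afmstate
implements a complete simulation-to-inference pipeline for interpreting such
images: a collision-detection image simulator for coarse-grained bead
models, a line-scan lag noise model, PCA + Gaussian-mixture definition of
ordered conformational states, a multitask vision-transformer autoencoder
that denoises images while classifying the conformational state, and
exhaustive-grid rigid-body fitting by pixel correlation as the conventional
baseline. This vignette records the models, the tunable parameters, and the
design decisions, in the package's own words.

## The imaging model

A molecule is a set of spheres: one bead per amino-acid residue at its
C-alpha position, one bead per lipid phosphate (acyl chains omitted). The
default amino-acid bead radius is 0.38 nm — the conventional C-alpha bead
spacing — for every residue type, because no standard residue-resolved
table exists for this one-bead representation; `readPDBEnsemble()` accepts
a named radius table for users who have one. The phosphate bead default is
0.235 nm (half the 0.47 nm diameter of a standard coarse-grained phosphate
bead). Tests never rely on the defaults; they pass explicit radii.

The tip is a cone of half-apex angle $\Theta$ capped by a sphere of radius
$R$, treated as infinitely tall (molecules are orders of magnitude shorter
than real tips). For each pixel the tip descends until it first touches a
bead of radius $r$ whose center is at lateral distance $d$ from the tip
axis and height $z$:

$$
h = \begin{cases}
z + \sqrt{(R+r)^2 - d^2} - R, & d \le (R+r)\cos\Theta \quad\text{(cap)}\\[4pt]
z + \dfrac{R + r - d\cos\Theta}{\sin\Theta} - R, & \text{otherwise (flank)}
\end{cases}
$$

The pixel value is the maximum over beads, floored at 0 (the bare stage).
The two branches agree exactly at the crossover; the test suite verifies
both this and agreement with a brute-force oracle that discretizes the tip
profile and lowers it numerically.

**Pose and stage conventions.** A pose is (x, y, $\phi$, $\theta$, $\psi$):
rotations are applied about the model centroid sequentially about the fixed
z-, x- and y-axes (by $\psi$, $\phi$, $\theta$), i.e. extrinsic
composition $R_y R_x R_z$ — the stated order of the underlying protocol;
whether that protocol meant intrinsic axes is not documented, so the
extrinsic reading was chosen and fixed. The centroid is the rotation center
so the molecule stays in frame under rotation. After rotation and lateral
translation the model is shifted along z so that its lowest point is the
stage (z = 0). The literal convention "minimum z-coordinate" applied to
bead *centers* would sink half of the lowest bead below the stage, so the
default uses bead *surfaces* (`min(z - r) = 0`); the center-based mode is
available as `stage = "center"` for fidelity comparisons.

Pixel (i, j) (row i counted from the bottom) has its center at
`origin + (j - 1/2, i - 1/2) * pixelSize`; the working grid is 36 × 36
pixels at 0.8 nm/pixel, the resolution regime of the motivating
experiments.

## Line-scan lag and measurement noise

An HS-AFM frame is scanned line by line along the fast x-axis; between
lines the molecule diffuses. `renderWithScanLag()` draws for every scan
line an independent perturbation of the *initial* pose — displacements are
taken from the t = 0 pose, not accumulated, deliberately a static-reference
approximation rather than a cumulative random walk — renders that line with
the perturbed pose, and assembles the lines (bottom row to top, each line
including the first drawing its own perturbation). Components are sampled
from zero-mean normals with variances $s\,\sigma_i^2$ and truncated by
*rejection resampling*: (dx, dy) jointly until
$\sqrt{dx^2+dy^2} \le w\,\Delta r_{\max}$, each angle independently until
within $w$ times its bound. Rejection (rather than clipping) preserves the
normal shape inside the admissible region and makes the distribution tend
to uniform on it as $s$ grows — the test suite checks the truncated-normal
variance at the reference parameters and the near-uniform limit at
$s = 10$.

The reference noise set (class defaults of `ScanNoiseParams()`):
$\sigma_x^2 = \sigma_y^2 = 0.81\ \mathrm{nm}^2$,
$\sigma_\phi^2 = \sigma_\theta^2 = 6.25\ \mathrm{deg}^2$,
$\sigma_\psi^2 = 25\ \mathrm{deg}^2$, $\Delta r_{\max} = 1.2$ nm,
$\Delta\phi_{\max} = \Delta\theta_{\max} = 5$ deg,
$\Delta\psi_{\max} = 10$ deg, $s = w = 1$. Measurement noise is additive
i.i.d. Gaussian per pixel with $\sigma_N$ drawn uniformly from the grid
0–0.3 nm in 0.01 nm steps, applied at data-loading time (never baked into
stored images) and without clamping.

Rotational perturbations act on Euler angles, which is not isotropic
diffusion on SO(3); with tilts restricted to ±20° the bias is small, and a
rigorous SO(3) treatment is out of scope.

## Conformational states

States are defined on the ensemble, not on images: conformers are
rigid-body superposed (Kabsch, SVD) onto the first frame — removing
translation and rotation from the state definition — flattened, and
decomposed by PCA. Clustering uses the first six principal components
(configurable) under full-covariance Gaussian mixtures; the cluster count
is the BIC optimum among candidate counts whose every cluster holds at
least a minimum occupancy (default 1% of frames). Initialization is
mclust's deterministic model-based hierarchical agglomeration, so the fit
is reproducible without restarts. Labels are then permuted so the per-state
mean of PC1 is non-decreasing — state 1 to K follows the conformational
transition — and each state is represented by the member nearest to its
cluster mean in the retained PC subspace. Within-state statistics use mean
pairwise superposed RMSD over up to 200 members (an evenly spaced
deterministic subsample beyond that); between-state distances are
center-to-center RMSDs of adjacent states. Whether RMSDs should be
re-superposed per pair is not externally fixed; the package always
superposes.

## The synthetic hinge fixture

Real ensembles come from MD; the package ships a generator whose output
stands in for one. Two rigid arms of 12 beads (radius 0.8 nm, length 6 nm)
share a pivot bead in the stage plane; state k opens the hinge to the k-th
of K angles evenly spaced over 40–120°, and every frame adds i.i.d.
Gaussian jitter (0.15 nm) to all bead coordinates. Defaults: K = 4, 250
frames per state, fully seeded. The geometry was sized once so that a
36 × 36 image at 0.8 nm/pixel resolves the motion (adjacent states differ
by ≈ 27° of opening, several pixels of arm displacement) and desk-scale
training converges in minutes. What the fixture does *not* emulate: real
side-chain texture, tip-sample elasticity, conformational kinetics, or the
fine state spacing of a real transition — so passing tests demonstrate
pipeline correctness and qualitative behaviour, not instrument-grade
accuracy on proteins. `linearMorph()` provides straight-line Cartesian
interpolation between two conformers (endpoints exact) for probing
classifier uncertainty on out-of-ensemble structures, and
`makeReferenceScene()` mounts the hinge above a flat phosphate-bead ring to
mimic the membrane-disc-on-stage geometry that motivates the ±20° tilt
limits.

## Dataset production

`buildDataset()` draws frames uniformly from the ensemble, samples tip and
pose from the discrete grids (R: 1.0–3.0 nm step 0.1; Θ: 5–30° step 1;
φ, θ: ±20° step 1; ψ: ±180° step 1), renders the ground-truth image and
the scan-lag-distorted image, records a σ_N level, and writes tar shards
whose members follow the `key.role.ext` convention so streaming loaders
group pairs. White noise and the ±3-pixel joint shift augmentation are
applied at load time, so one stored dataset serves many noise levels.
Min–max normalization of *both* pair members uses the noisy member's
extrema — the quantities available at inference time, which the denoised
output is rescaled by; normalizing the target by its own extrema would make
the reconstruction scale unobservable at inference. Generation is
deterministic per (seed, shard index) via labelled substreams, so shards
can be produced independently without reshuffling each other's draws.

## The multitask autoencoder

The network is a pre-norm vision transformer: 6 × 6 patches of a 36 × 36
image (36 patch tokens + 1 class token, learned positional embeddings),
an encoder, and two branches — a classifier (2 further transformer blocks
and a linear head on the class token) and a decoder (linear projection to a
narrower width, decoder blocks, per-token linear back to pixels). The
reference architecture is a 12-layer/512-dim encoder with an 8-layer/256-dim
decoder — deliberately asymmetric so the encoder learns semantic structure
rather than memorizing pixels; the tested desk-scale configuration is
4/128 with a 2/64 decoder. Patch size (6 px), heads (8; 4 at desk scale),
MLP ratio (4), GELU activations and the classifier depth are declared
package defaults, not reproductions of an external configuration. The loss
is $L = \alpha L_d + \beta L_c$ with $L_d$ the mean squared error between
normalized ground-truth and denoised images, $L_c$ the cross-entropy of the
state prediction, and $\alpha = 100$, $\beta = 1$ balancing the two scales.
Optimization is AdamW (weight decay 1e-4, no decay on embeddings, biases or
layer-norm parameters) with linear warmup to the peak learning rate
followed by cosine decay to zero.

Two implementations of the same mathematics exist: a pure-R
double-precision reference (verified by finite-difference gradient checks)
and a compiled float32 engine (single precision is the conventional working
precision for this model family) that the trainer uses by default; the test
suite cross-checks the engine against the reference to float32 accuracy.
Divergent (non-finite) loss aborts training and returns the last
finite-loss state.

**Desk-scale training protocol** (`deskTrainConfig()`). The tested
desk-scale recipe trains the 4/128–2/64 model for 10 epochs on 5,000
fixture pairs (10% held out), batch 12, peak learning rate 1e-3 with one
warmup epoch, on the stored scan-lag pairs directly — the load-time shift
augmentation and white-noise injection are switched off. The small batch is
deliberate: with epochs and data fixed, batch size sets the optimizer step
count, and at ~10^3 steps the model is still underfitting, so more steps
win. The stochastic load-time transforms are off for the same reason — at
this step count they dominate the gradient signal and stall the classifier
near chance, while at the reference scale (millions of images, ~10^5
steps) they are affordable and valuable; both remain available as
`trainAE(augment =, addNoise =)` switches. Robustness to white noise is
still *measured* (the evaluation applies test-time σ_N), it is simply not
trained against at this scale. Under this protocol the desk model reaches
roughly 81% exact-match on clean held-out images (99.8% within ±1 state;
a converged linear classifier on the same pixels reaches 62%), and it is
still improving when the 10-epoch budget ends — the desk-scale figures
quantify the pipeline, not the architecture's ceiling.

**Attention rollout** multiplies, across the encoder and classifier layers
(span configurable, since "the classifier's attention" is ambiguous when
the classifier sits on top of a shared encoder), the head-averaged
attention matrices blended with the identity — $\tfrac12(A + I)$,
row-renormalized — and reads out the class-token row, reshaped to the patch
grid and upsampled to pixels, normalized to [0, 1]. The 0.5-blend is one of
several rollout conventions; it is fixed and stated so maps are comparable.

**Transfer.** `transferInit()` copies every tensor whose name and shape
match into a freshly initialized model (the classifier output layer stays
fresh when the state count differs) and can freeze the embedding + encoder.

## Rigid-body fitting

The conventional baseline scores a candidate structure against an image by
the Pearson correlation over pixels and searches exhaustively: every
candidate (typically the K state centers), every grid value of ψ (±180°,
5° steps), φ and θ (±30°, 5° steps), optionally gridded probe parameters
(R ∈ {1, 2, 3} nm, Θ ∈ {10, 20, 30}° when the probe is unknown), and every
integer pixel shift within ±3 px. The shift search translates the rendered
image with zero fill rather than re-rendering — identical values for
interior content at a 49× saving; whether the original protocol re-rendered
per shift is not documented, and the pixel-shift reading was chosen. The
search order and strict-improvement argmax are fixed (candidate, ψ, φ, θ,
R, Θ, shift), so ties break deterministically toward the lowest state and
earliest grid point. `fitAfterDenoise()` runs the autoencoder first,
restricts candidates to the predicted state's center and fits the pose
only — the noise-robust protocol.

## Experimental image preprocessing

The support lattice's height is estimated as the mean over pixels that are
neither lattice holes nor molecule; holes are filled with that value; the
image mean is subtracted; the molecule's intensity-weighted centroid is
moved to the central pixel by an integer shift; and the frame is cropped or
zero-padded to 36 × 36. How holes and the molecule are identified is not
fixed by the source protocol; the package defaults to robust thresholds at
median ± 3 MAD with user-overridable mask arguments, which keeps the
pipeline deterministic and auditable. Heights remain in nm end to end.

## Numerical choices and degenerate inputs

- Constant images: min–max normalization maps them to zeros and records
  vmin = vmax; the correlation coefficient is undefined and raises an
  error rather than returning a value.
- Layer-norm epsilon 1e-5; cross-entropy probabilities floored at 1e-12.
- The all-zero perturbation short-circuits (s = 0 or w = 0), so the
  degenerate scan-lag render is bit-identical to the static render (both go
  through the same compiled pose-and-render kernel).
- Rank-deficient ensembles reduce the retained PC count with a warning.
- All randomness descends from one seed via labelled substreams
  (`deriveSeed`), so adding workers or reordering stages never changes
  another stage's draws; every seed stays below 2^31.

## Problem sizes used by the checks

The acceptance checks run the pipeline at sizes chosen as this package's
desk-scale study conditions: the default hinge fixture (K = 4, 1,000
frames) for clustering; 100 grid-aligned renders plus a smaller
distortion-added set for rigid-body fitting; 5,000 training pairs and 10
epochs for the desk-scale network. These sizes are the package's own
defaults for a laptop-class reproduction; the reference-scale protocol
(19 states, millions of images, 20 epochs) is constructible with the same
functions.

## Known limitations

- No elastic tip-sample deformation, double-tip artifacts, or drift.
- Scan-lag perturbations are independent per line (no cumulative walk) and
  Euler-angle based (no SO(3) diffusion).
- The desk-scale accuracy figures quantify the pipeline on the synthetic
  hinge, not on proteins; the fixture's states are far better separated
  than a real fine-grained transition.
- The effective per-residue radius table is a single default value unless
  the user supplies one.
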