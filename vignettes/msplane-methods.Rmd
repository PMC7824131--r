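---
title: "Detecting the fetal mid-sagittal plane in 3D ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the fetal mid-sagittal plane in 3D ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msplane)
```

## The problem

First-trimester biometry (nuchal translucency, crown–rump length) is read off
the fetal **mid-sagittal plane** (MSP): the plane splitting the head into
mirror-symmetric left and right halves, passing through the nasal tip, nasal
bone, nuchal translucency and the dark central diencephalon.  Finding this
plane in a 3D ultrasound volume by hand is slow and operator-dependent.
`msplane` implements a two-stage automatic detector:

1. **Seed-point cascade** — four small 2D networks locate the head centre
   (the diencephalon landmark): a U-Net with an atrous-spatial-pyramid-pooling
   (ASPP) bottleneck segments the landmark in the sagittal view, two
   object-detection networks place the head box in the axial and coronal
   views, and a second segmentation network refines the through-plane
   coordinate.  The five refinement steps are run in a fixed order by
   `detect_seed()`.
2. **Adversarial mask generator** — an 80³ cube cropped around the seed is
   mapped by a symmetric 3D convolutional autoencoder to a same-sized soft
   mask marking the voxels of the MSP.  Training pairs a Wasserstein
   critic with gradient penalty (WGAN-GP) with a voxelwise cross-entropy
   term:

   $$L_G = -(1-w)\,\mathbb E[C(x')] + w\,L_{ce}, \qquad
     L_C = \mathbb E[C(x')] - \mathbb E[C(y')] +
           \lambda\,\mathbb E[(\lVert\nabla_{\hat x'}C(\hat x')\rVert_2-1)^2],$$

   with $w = 0.8$, $\lambda = 10$, $\hat x = \alpha y + (1-\alpha)x$,
   $\alpha\sim U(0,1)$ per sample, and $x'$ the **combined** two-channel
   critic input `(mask * volume, volume)` built by `combine()`.

Post-processing fits a plane to the mask by weighted total least squares
(`fit_plane_from_mask()`), maps the initial sagittal slice lattice onto it
through the rigid decomposition $M = TR$ (`transform_between_planes()`), and
resamples the volume trilinearly to produce the final 2D MSP image
(`extract_msp_image()`).

## Coordinate and plane conventions

All geometry is in **0-based voxel units**; physical spacing travels as
metadata only.  Axis 1 (`x`) is the left–right axis, so a mid-sagittal plane
has its normal dominantly along `x`; axes 2–3 are the in-plane sagittal
coordinates, with axis 2 the "horizontal" direction used for left/right flip
alignment.

A plane $ax+by+cz+d=0$ is stored as a **unit-norm 4-vector** with the first
nonzero component of $(a,b,c)$ positive (`normalize_plane()`).  Without such
a convention the coefficient-space metrics below would be meaningless, since
the raw coefficients are only defined up to scale and sign.

The labelling convention mirrors manual annotation: the sagittal plane
through the seed point is tilted by $\theta_{axi}$ (as seen on axial
sections) and then $\theta_{cor}$ (as seen on coronal sections).  Axis
namings for this construction are easy to state inconsistently (rotating a
plane about its own normal is a no-op), so the package fixes one
self-consistent reading: the normal is
$R_y(\theta_{cor})R_z(\theta_{axi})\,(1,0,0)^T$.  Under this convention the
yaw angle $\arctan(b/a)$ of the constructed plane equals $\theta_{axi}$
exactly, and `angles_from_plane()` is an exact inverse below 90°.

**Metric origin.**  The four pair metrics (included angle, coefficient
distance, yaw, roll) act on coefficient 4-vectors, whose `d` component
scales with the distance of the plane from the origin.  With a volume-corner
origin, `d` (~40 voxels for a centred plane in an 80³ crop) dominates the
4-vector and compresses the included angle toward zero.  The package
therefore evaluates pair metrics on planes re-expressed with the **crop
centre (seed point) as origin** (`recenter_plane()`), consistent with a
labelling convention in which the seed point becomes the origin.  This is
the stricter choice: a pure 5° normal rotation measures ≈5° at the seed
origin but ≈0.3° at a corner origin.

## Numerical choices

* **Rasterization**: a voxel belongs to a plane mask iff its centre lies
  within `half_thickness = 0.5` voxel of the plane (a one-voxel digital
  plane).  Mask thickness is not prescribed anywhere authoritative; 0.5 is
  the thinnest value that leaves no holes.
* **Plane fitting**: voxels above threshold are a weighted point cloud; the
  normal is the smallest-singular-vector of the centred, `sqrt(weight)`-
  scaled scatter.  Fewer than 3 support voxels is an error, as is collinear
  support (second singular value ≈ 0).  In the full pipeline the threshold
  is **adaptive** — half the soft mask's peak value — so orientation can be
  read off a confident ridge long before absolute probabilities cross 0.5.
* **Slice extraction**: trilinear interpolation by default,
  nearest-neighbour on request; out-of-volume samples are 0.  Extraction is
  invariant to rescaling of the plane coefficients because every entry point
  normalizes first.
* **Included angle**: computed as $2\arcsin(\lVert v_1 - v_2\rVert/2)$ on
  sign-aligned unit 4-vectors, which is algebraically $\arccos(v_1\cdot
  v_2)$ but exact near zero (identical planes give exactly 0°).  The
  identity $d^2 = 2(1-\cos\theta)$ ties the coefficient distance to the
  included angle and is verified property-style in the tests.
* **Round-trip accuracy is assessed on normal and offset separately.**  At
  the seed origin, an offset error of only 0.005 voxel already contributes
  ≈0.3° to the 4-vector included angle, so a combined-angle criterion would
  be dominated by sub-voxel offset noise rather than orientation.  The
  rasterize→fit validation therefore bounds the angle between plane
  *normals* (< 0.1°) and the plane offset at the seed (< 0.5 voxel)
  separately; the fitted estimator achieves ≈0.01° and ≈0.01 voxel on 80³
  masks.
* **Agreement statistics**: paired differences get mean, SD, a t-based 95%
  CI ($n-1$ df), Pearson correlation, a paired t-test and Bland–Altman
  limits $\text{bias} \pm 1.96\,\text{SD}$.  Zero-variance differences
  report the p-value as not applicable rather than propagating NaN.

## The neural-network engine

No deep-learning framework is required: the package ships a small,
vectorised reverse-mode engine.  Activations are `(features × batch)`
matrices in channel-major layout; each convolution precomputes an integer
im2col index map at construction time, so a forward pass is one gather plus
one BLAS GEMM, and the backward pass is the corresponding scatter
(`rowsum`).  Transposed convolutions are implemented directly as the adjoint
scatter, keeping their im2col buffers on the coarse side of the layer.  All
layer gradients — including strided, dilated and transposed convolutions,
max-pooling and the U-Net's branched wiring — are verified against central
finite differences in the test suite.

**Gradient penalty, double backprop.**  The penalty value uses the exact
analytic input gradient of the reduced critic.  Updating the critic,
however, needs $\nabla_\theta \lVert\nabla_x C(x;\theta)\rVert$, a mixed
second derivative.  The engine evaluates it by a central finite difference
of the critic along the (stop-gradient) normalised input-gradient direction
$\hat u$:
$\lVert g\rVert = g\cdot\hat u \approx [C(x+\varepsilon\hat u) -
C(x-\varepsilon\hat u)]/2\varepsilon$, whose parameter gradient needs only
ordinary first-order backprop on the two shifted inputs.  Because the critic
is piecewise smooth (leaky ReLU, max-pooling), $\varepsilon$ must stay below
the distance to the nearest activation switch: at $\varepsilon = 10^{-4}$
the approximate gradient matches brute-force numerical differentiation of
the exact penalty to cosine similarity 1.000; at $10^{-3}$ kink crossings
corrupt it badly.  The default is `fd_eps = 1e-4`.

**Interpretation of the critic output.**  The critic emits a latent vector
with a final sigmoid rather than a scalar.  Every expectation in the losses
reduces that vector by its mean, and the gradient penalty differentiates the
reduced scalar; this is the single largest interpretation risk in the design
and is kept deliberately simple.  The sigmoid bounds the Wasserstein
surrogate; it is retained as described rather than "repaired" to the usual
unbounded critic.

**Architecture widths are configuration.**  The clinical-scale defaults
(80³ crops, encoder channels 16/32/64/64, latent 200) reflect the
clinical-scale design; the desk-scale runs in the tests and acceptance
script use 32³ crops with encoder channels 8/16/16/16 and latent 128 so a
full training fits a single CPU.  The critic mirrors the generator encoder's
channel widths (a stated architectural constraint); each critic block
max-pools before convolving, which keeps its buffers at the halved grid.

## The synthetic phantom

The clinical volumes behind this design are private, so every stage is
exercised on synthetic fetal-head phantoms with known ground truth
(`generate_phantom()`):

* an ellipsoidal bright shell ("skull", semi-axes 0.28/0.35/0.32 of the
  smallest extent) whose frame is rotated so the shell is mirror-symmetric
  about the ground-truth plane;
* a dark central blob (the "diencephalon") at the seed point (radius 0.07
  of the smallest extent) — the segmentation target of stage 1;
* four pairs of bright features placed mirror-symmetrically about the
  plane, making it the unique maximal-symmetry plane;
* one asymmetric "nose" marker outside the shell on the head side, so
  left/right flip alignment is learnable and testable;
* Gaussian blur (σ = 0.8 voxel) followed by multiplicative unit-mean
  gamma speckle (variance `noise_level`, default 0.05), then clipping to
  [0, 1].

Tilt angles are uniform on ±30°, matching the usual inclusion baseline for
oblique acquisitions; the boundary of the ±30° exclusion filter is treated
as inclusive.  Geometry parameters are test fixtures, not anatomical claims;
the phantom has no shadowing, no probe geometry and no quantitative claim of
clinical image statistics, so passing tests demonstrate the pipeline's
mechanics and its behaviour under speckle-like degradation — not clinical
performance.

## Training schedules and problem sizes

Stage 1 trains the segmentation networks with Adam (batch 10, binary
cross-entropy) and the detection networks with momentum SGD (batch 5,
momentum 0.9, weight decay 5·10⁻⁴, cross-entropy + Huber).  Stage 2 trains
generator and critic alternately (one step each) with Adam at learning rate
10⁻⁴, β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸, batch 8.

The package's reference desk-scale experiment — run by
`scripts/acceptance.R` and mirrored in the test suite — uses 200 training
phantoms at 32³ for ~30 epochs for the GAN and 150 phantoms for the seed
cascade, with 50 held-out phantoms for evaluation.  On these conditions the
seed cascade recovers held-out seed points to well under 2 voxels median
error.

**A known limitation of the desk-scale GAN schedule.**  At learning rate
10⁻⁴, 30 epochs of 200 samples are 750 optimisation steps.  Adam moves each
parameter by roughly the learning rate per step, so the whole schedule
displaces parameters by ~0.075 — several times less than what the same
architecture demonstrably needs to map volume orientation to mask
orientation (in controlled supervised runs at 10⁻³ the identical network
solves the task in ~150–300 steps).  A clinical-scale system would train orders of
magnitude longer; the desk-scale schedule reproduces the *procedure*
faithfully but is expected to undertrain, and the
end-to-end plane-recovery figure reported by the acceptance machinery should
be read with that in mind.  The adaptive fitting threshold recovers the
orientation signal as early as possible, and all other stages (seed
detection, geometry, metrics, agreement) meet their quantitative surfaces
comfortably.

## Cross-validation and the two arms

`run_cross_validation()` assigns included cases to near-equal seeded folds,
trains both stages per fold, and evaluates the held-out fold case by case
(a conventional near-equal partition).
The **semi-automatic** arm replaces stage 1 with the annotated seed point
and is compared against the fully automatic arm with the Bland–Altman
machinery (`agreement()`), mirroring the standard interchangeability
analysis.  A one-way ANOVA across folds checks that no fold behaves
differently on any of the four metrics.

Everything that consumes randomness — phantom generation, both training
stages, fold assignment, gradient-penalty interpolation — derives from
explicit integer seeds, and seeded runs are bit-reproducible; the test suite
asserts this for each stage.
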