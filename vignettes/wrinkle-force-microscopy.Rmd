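---
title: "Wrinkle force microscopy: models, assumptions and design choices"
author: "wrinklefm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrinkle force microscopy: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrinklefm)
```

## The problem

Adherent cells pull on their substrate through focal adhesions. On a soft
silicone gel whose surface has been stiffened by plasma oxidation, this
contraction does two things at once: it displaces fiducial beads embedded
in the surface (the classical traction force microscopy readout), and it
buckles the stiff skin into micrometre-scale wrinkles that are directly
visible in an ordinary micrograph. Wrinkle force microscopy (WFM) exploits
the second channel: once an image-to-image translator has been trained on
simultaneously measured (image, traction) pairs, the cellular force
distribution can be read off a single still image, with no bead tracking
and no reference frame after cell removal.

`wrinklefm` implements the full computational pipeline around this idea:

1. **TFM** — the forward and inverse elastic problem connecting traction
   and surface displacement, plus a particle-image-velocimetry (PIV)
   displacement estimator;
2. **wrinkle analysis** — skeleton length, spectral principal direction,
   topology, and the contractile stress-tensor statistics of a traction
   field;
3. **wrinkle mechanics** — the bilayer buckling model linking wavelength,
   amplitude and onset strain to the skin/elastomer stiffness ratio;
4. **a synthetic-cell generator** — physically consistent (image,
   traction) pairs so that every stage is testable without experimental
   data;
5. **the force codec and error metrics** — the arctangent force-to-gray
   mapping and the weighted magnitude/angle errors;
6. **the translator** — a U-Net-style generator and patch discriminator
   trained with the conditional-adversarial + L1 objective, and an
   L1-only baseline.

## Elastic model and the inverse problem

The substrate is treated as an isotropic, linearly elastic half-space
(Young's modulus `E`, Poisson ratio `nu`; defaults 5400 Pa and 0.5). The
surface displacement produced by a tangential traction field is the
convolution of the traction with the Boussinesq surface Green's function

$$G(r) = \frac{1+\nu}{\pi E r^3}
  \begin{pmatrix} (1-\nu)r^2 + \nu r_x^2 & \nu r_x r_y \\
  \nu r_x r_y & (1-\nu)r^2 + \nu r_y^2 \end{pmatrix},$$

whose analytic Fourier transform,
$\tilde G(k) = \tfrac{2(1+\nu)}{E k^3}
[(1-\nu)k^2 I + \nu (k^2 I - k k^T)]$ in components, is evaluated on the
discrete wavevector lattice (`fourierKernel`). Fourier-transform traction
cytometry then solves, wavevector by wavevector,

$$\tilde t = (\tilde G^T \tilde G + \lambda^2 I)^{-1} \tilde G^T \tilde u,$$

a Tikhonov-damped least-squares inversion (`solveTractionFTTC`).

Numerical choices worth knowing about:

* **Zero-mean convention.** The $k=0$ mode is removed in both directions:
  an adherent cell exerts no net force on its substrate. In padded mode
  the crop is re-centred so the returned window also sums to zero.
* **Pixel-box model.** The solvers multiply the kernel by
  $\mathrm{sinc}(k_x p/2)\,\mathrm{sinc}(k_y p/2)$, i.e. they model the
  gridded traction as constant over each $p \times p$ cell rather than as
  a trigonometric interpolant. This makes the spectral operator agree
  with direct real-space quadrature of the convolution integral to
  better than 2% on smooth fields (the package tests verify this against
  an independent cell-averaged summation oracle); the unfiltered analytic
  kernel is available via `fourierKernel(..., boxFilter = FALSE)` and
  decays as $1/|k|$.
* **Boundary handling.** `"periodic"` mode is the cyclic convolution on
  the field's own lattice — it forms an exact inverse pair with the
  forward model (round-trip error below $10^{-6}$ at $\lambda = 0$) and
  is the mode of choice for oracle tests. `"padded"` mode zero-pads by a
  factor two per axis to suppress wrap-around and is the default for
  experiment-like data. Zero-padding the *displacement* in the inverse
  direction is approximate (the true displacement does not vanish outside
  the field of view); this is one of the dominant error terms of the
  padded inversion and a known limitation.
* **Regularization scan.** `selectLambdaLCurve` scans a logarithmic
  $\lambda$ grid (29 points over 7 decades scaled to the kernel magnitude
  by default), records residual and solution norms spectrally, and picks
  the corner of the log–log curve as the maximum of a spline-smoothed
  curvature, falling back to the maximum chord-distance point when the
  curvature signal is flat. Because the per-wavevector system is square
  and invertible, the residual vanishes as $\lambda \to 0$ for *any*
  data — the classical L-curve therefore has no corner for noise-free
  data. The scan detects this case through the spectral roughness of the
  unregularized solution (measurement noise inflates the high-wavevector
  power; smooth consistent data do not) and then returns the largest
  $\lambda$ still at the residual floor.

## PIV

`pivDisplacement` is a multipass block-matching PIV: cyclic FFT
cross-correlation of square interrogation windows (default 32 px, step
16 px), three-point Gaussian sub-pixel peak fit with a parabolic fallback,
3×3-median outlier replacement, and predictor–corrector passes that warp
the deformed image back by the current estimate so later passes measure a
residual near zero. Window deformation removes the bias that displacement
gradients induce in single-pass correlation; an optional Gaussian window
weighting (`weightSigma`) narrows the effective averaging footprint
further. Windows with no texture are flagged `NaN` rather than guessed.
On rendered bead images with uniform shifts the estimator is accurate to
well under 0.15 px; on full cell-scale displacement fields the remaining
error (a few percent of the field, spatially correlated with the
displacement curvature) is what limits the end-to-end
traction-reconstruction chain to roughly 20–30% relative error — the
inversion amplifies correlated displacement error by a factor of about
2.5 on the default 26×26 problem.

## Wrinkle geometry and traction statistics

The mean traction is $\bar f = \frac1M \sum_m |f_m|$. The contractile
stress tensor is the symmetrized first moment of the traction about the
image center,

$$S_{ij} = \frac{1}{2M} \sum_m \{ n_j f_i + n_i f_j \},
  \qquad n = \frac{x_m - x_0}{|x_m - x_0|},$$

whose dominant eigenvalue $f_P$ is negative for a contractile cell; the
isotropy $I = |f_P / f_P^{\min}| \ge 1$. Nodes coinciding exactly with
the center (at most one, on odd grids) are skipped since their direction
vector is undefined.

Angle conventions: arrays are stored in image order (row index downward),
but every reported angle is in degrees, counter-clockwise from $+x$ in a
y-up physical frame; the single y-flip happens inside the angle-producing
operations. Principal directions are axial quantities folded into
$[0, 180)$, so `angleDifference` lands in $[0, 90]$.

Wrinkle length is the pixel count of the Zhang–Suen skeleton (thinning
shortens free line ends by a pixel or two — the tests allow for that).
The wrinkle principal direction comes from the Hann-windowed 2-D power
spectrum: power is averaged in 2° angular bins over the half-plane
(averaged, not summed, because the square lattice samples angles
non-uniformly), the DC disc below 2 cycles/image is masked, and the
reported direction is perpendicular to the strongest spectral direction.
Masks with fewer than 10 foreground pixels, or spectra whose maximum bin
is less than 1.5× the median bin, return `NA` (no dominant direction).
Topology counts 8-connected regions of at least 20 px: one region is
"clustered", several are "dispersed". Roundness is $4\pi A/P^2$ with the
perimeter estimated from the 4-neighbour boundary-edge count scaled by
$\pi/4$ (exact for digitized disks), clamped to $(0, 1]$.

## Bilayer buckling mechanics

A stiff oxidized skin (modulus $E_p$, thickness $h$) on a soft elastomer
($E_m$) buckles under compression with

$$\lambda / h = 2\pi (E_p / 3E_m)^{1/3}, \qquad
  A/h = (\varepsilon/\varepsilon_c - 1)^{1/2}, \qquad
  \varepsilon_c = -\tfrac14 (3E_m/E_p)^{2/3}.$$

Both strains are carried as negative numbers (compressive convention);
below onset the amplitude is zero, not complex. Worked numbers the
package reproduces exactly: a wavelength-to-thickness ratio of 30 implies
a stiffness ratio near 300 and an onset strain near $-0.01$; requiring 20
wavelengths across a 100 µm cell at $h = 100$ nm bounds the ratio at
1500; at the experimental maximum strain $-0.05$ the amplitude on a
100 nm skin is 200 nm. When two substrates share the same stiffness
*ratio*, the wrinkle-generation conditions coincide and a trained
predictor transfers by scaling every traction by $E^{new}/E^{ref}$
(`rescalePrediction`).

## The synthetic-cell generator

`sampleTraction` emulates a contractile adherent cell: 6–16 adhesion
sites concentrated at the two poles of a random ellipse (aspect ratio
1.3–3, semi-major axis ~25 µm), each pulling toward the cell center as a
Gaussian force spot (σ = 5 µm) with peak magnitudes scattered around the
traction scale (default 200 Pa, which puts the population mean traction
near the ~50 Pa scale typical of smooth-muscle cells on soft silicone).
The field is then balanced exactly — mean removal for zero net force and
subtraction of a rigid-rotation pattern for zero net torque — so the
forward model's zero-mean convention is satisfied to machine precision.
The 26×26 grid at 3.44 µm spacing matches the force-observation
resolution of the experimental pipeline.

`renderWrinkles` draws sinusoidal ridges perpendicular to the local
principal force direction (structure-tensor orientation, smoothed over
about a fifth of the field of view so wrinkle trains span the cell), with
the wavelength given by the buckling relation. Two deliberate modelling
choices:

* **Extinction floor**: fields whose mean traction is below 10 Pa produce
  no wrinkles at all, mirroring the observed detection floor.
* **Built-in linear length law**: the wrinkled region is the
  strongest-stress area above the floor, sized so that total ridge length
  grows linearly with mean traction. The linear relation between wrinkle
  length and force is an experimental observation, and the generator
  encodes it by construction — which is exactly why the package's
  population-level tests (Spearman ρ > 0.8, wrinkle–traction angle
  difference concentrated at 90°) validate the *analysis* operators, not
  the biology. A rendered wavelength below the raster resolution limit is
  clamped at 4 px so the ridges stay representable; orientation and
  extent are unaffected.

`renderBeadImages` scatters fluorescent beads (default 0.3 /µm²) on an
oversampled pixel grid (default 16× the force grid, 0.215 µm pixels),
renders Gaussian point-spread spots, and warps bead positions by the
forward displacement, with optional Gaussian position noise (0.02 µm) and
8-bit image noise. What the generator does *not* emulate: phase-contrast
optics, bead clumping or detachment, focal drift, out-of-plane
deformation, and the morphological diversity of real cell lines. Passing
tests on synthetic data therefore demonstrate internal consistency of the
pipeline, not performance on real micrographs.

`buildDataset` writes `n` base cells and their four exact 90° rotations
(force components co-rotated as $(f_x, f_y) \to (-f_y, f_x)$), so 63 base
cells give exactly 252 pairs; the train/test split holds out whole base
cells, never individual rotations of a training cell.

## Codec and error metrics

One force component at a time is encoded as
$I(f_d) = a\,\mathrm{atan}(f_d/b) + I_{mid}$ with $a = 81.2$, $b = 50$ Pa,
$I_{mid} = 127.5$ — a strictly increasing odd map whose asymptotes sit
just outside the 8-bit range, so every intensity 0…255 decodes to a
finite force. The y-component is handled by the rotation trick: the
translator always predicts the x-component, and is fed the 90°-rotated
image to obtain the (co-rotated) y information (`axisSplitRotate`,
`predictTraction`).

The magnitude error $\varepsilon_f$ weights each node's relative error by
$\omega_m = f_m^{true}/\bar f$; the weight cancels the per-node division
exactly, so the implementation uses the reduced, singularity-free form
$\sum |f^{pred}-f^{true}| / (M \bar f)$ (an algebraic-equivalence test
against the literal form guards this). The direction error
$\varepsilon_\theta$ uses the full-quadrant arctangent with differences
wrapped into $[0, 180]$ by default — the principal-value form printed in
the defining expression is quadrant-ambiguous; the unwrapped variant is
selectable (`wrap = FALSE`). `correlationR` pools both components of all
nodes into one Pearson coefficient.

## The translator

The generator is an encoder–decoder with skip connections:
$\log_2(\mathrm{size}) - 2$ stride-2 4×4 convolution blocks (LeakyReLU,
instance normalization except on the first block) down to a bottleneck,
then nearest-neighbour ×2 upsampling with 3×3 convolutions and the
symmetric encoder activation concatenated at each scale, ending in a tanh
head. Nearest-up + convolution was chosen over transposed convolution to
avoid checkerboard artifacts; instance rather than batch normalization
because the batch size is 1. The discriminator scores overlapping patches
of the (input image, force image) 2-channel pair through four 4×4
convolution blocks. Channel widths default to 16 at full scale and 8 in
the desk-scale test configuration; depth and widths are not prescribed by
the published description beyond "U-Net-based" and "PatchGAN", so
standard image-translation widths are used and recorded in the
configuration snapshot.

The objective is the conditional-adversarial loss plus a weighted L1
term,

$$\mathcal{L}(G, D) = \mathbb{E}[\log D(x, y)] +
  \mathbb{E}[\log(1 - D(x, G(x)))] + \lambda L_1(y, G(x)),$$

with $\lambda = 100$; the discriminator maximizes the two log terms, the
generator minimizes the second plus the L1 distance, exactly as written
(the generator uses the saturating $\log(1-D)$ form, not the
$-\log D$ trick; with $\lambda = 100$ the L1 term dominates the
generator's gradient in any case). Training is batch-size-1 Adam
(learning rate $2\times10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.9$, 100
epochs at full scale) with alternating discriminator/generator updates;
probabilities are clamped to $(10^{-7}, 1-10^{-7})$ before the logs. The
`cnn_baseline` model is the identical generator trained on the weighted
L1 term alone. All convolution forward/backward passes are implemented in
compiled code (im2col + GEMM) with hand-derived gradients, verified
against numerical differentiation in the test suite; every random draw
flows through R's RNG, so one seed fixes initialization, shuffling and
the full loss trajectory bit-for-bit.

**Desk-scale regime.** The published accuracy of the method (pooled
correlation 0.84–0.88, magnitude error 38–41%, angle error 19–23°) was
obtained with 252 experimentally measured training pairs at 256 px and
100 epochs of GPU training; those numbers cannot be reproduced without
that dataset. The package's end-to-end check instead trains on 200
synthetic 64 px pairs (50 base cells × 4 rotations, 20 held-out cells)
for 30 epochs per model on one CPU — sizes chosen so the whole suite
stays convenient to run interactively — and verifies the scaled-down
targets: held-out pooled correlation at least 0.6, weighted angle error
at most 45°, and held-out L1 no worse than 1.05× the baseline's. In this
configuration the adversarial run reaches R ≈ 0.83 and ε_θ ≈ 16° and
edges out the baseline's held-out L1: the pure-L1 model starts
overfitting its held-out reconstruction after roughly 20 epochs, while
the adversarial term acts as a mild regularizer. Because the synthetic
wrinkles are a deterministic function of the traction, the synthetic
task is easier than the experimental one, and these numbers should not
be read as a claim about real micrographs.

## Known limitations

* The padded inverse treats unobserved displacement as zero; a
  support-constrained iterative inversion would be more faithful but is
  not implemented.
* PIV error on realistic displacement fields is spatially correlated, so
  regularization cannot fully remove it; the chain accuracy floor is
  ~20–30% relative L2, consistent with published error analyses of
  regularized FTTC.
* The wrinkle renderer is phenomenological (ridge trains with the right
  wavelength, orientation and extent); it does not solve the
  post-buckling elasticity problem, and herringbone or folding patterns
  are out of scope.
* The translator is trained and evaluated per input type (pseudo
  micrograph here; wrinkle masks would need their own training run).
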