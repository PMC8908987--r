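---
title: "Texture and shape descriptors for lung nodule characterization"
author: "noduleCAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture and shape descriptors for lung nodule characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleCAD)
```

# The problem and the model

Malignant pulmonary nodules grow fast. Fast growth disturbs both the
internal density of the nodule — its CT texture becomes heterogeneous —
and its outline, which becomes lobulated and spiculated instead of
smoothly spherical. noduleCAD turns these two clinical observations into
six quantitative descriptors of a segmented nodule inside a standardized
40 mm cubic volume of interest (VOI), resampled to isotropic 1 mm
voxels, and classifies the descriptor vectors with a two-stage stacked
autoencoder system.

Appearance (texture) descriptors:

* **Multi-view analytical LBP (ALBP).** The traditional local binary
  pattern thresholds the circular neighbourhood of a pixel at the centre
  value, so a single noisy voxel flips bits. The analytical variant
  instead resamples the neighbourhood at several radii ("levels"
  $R = 1..R_{\max}$), summarizes each level by five statistics (median,
  mean, population SD, min, max), and thresholds each statistic against
  its own mean over levels: $\mathrm{code}_m = \sum_l 2^{l-1}
  f(m(G_l) - \mu_m)$, $f(x) = \mathbf{1}[x \ge 0]$. Three resampling
  schemes are supported: `full_n` ($8R$ samples per level), `single_n`
  (always 8) and `average_n` ($8R$ samples averaged over 8 arcs, the
  default). The descriptor is the per-statistic code histogram over the
  nodule cross-section on 5 equally distributed views, concatenated
  (length $5 \times 5 \times 2^{R_{\max}} = 200$ at the defaults).
* **Fast 3D HOG.** Per-axis central-difference gradient volumes are
  cumulatively summed into integral gradient volumes, making the mean
  gradient of any box an 8-corner query. Each $3^3$-voxel cell casts one
  vote, weighted by gradient magnitude, into direction bins defined by
  the vertex directions of a platonic solid (default: dodecahedron, 20
  bins, full binning). The vote projects the gradient on all bin
  directions, subtracts the adjacency threshold (the dot product of
  neighbouring vertex directions), clamps negatives and keeps the three
  largest components, then rescales so the vote norm equals the gradient
  magnitude. Cell histograms are summed per block ($5^3$ blocks) and
  L2-normalized; the concatenation has length $125 \times 20 = 2500$.
* **MGRF Gibbs energy.** A translation-invariant Markov–Gibbs random
  field is trained on benign nodules only: HU values are quantized to
  $Q = 32$ levels over the training 1st–99th percentile range, and each
  clique family's potentials are the centred empirical configuration
  frequencies (the analytic first-order approximation of maximum
  likelihood). Families are the 13 pairwise offsets of the
  26-neighbourhood plus a 7-voxel star (centre + 6 face neighbours)
  whose configuration is the number of face neighbours at the centre's
  level. The per-voxel Gibbs energy is minus the sum of the potentials
  of all cliques containing the voxel; the descriptor is the normalized
  1000-bin histogram of in-mask energies over a fixed range (training
  0.5–99.5 energy percentiles). Benign-like texture gets low energy,
  unusual texture high energy; the histogram shape feeds the classifier
  either way, so no polarity is hard-coded.

Shape descriptors:

* **Multi-view peripheral sum curvature scale space (PSCSS).** Nodule
  cross-sections on 5 views are smoothed with Gaussians of increasing
  scale ($\sigma \in \{1, 2, 4, 8, 16\}$ px at 0.25 mm section pixels);
  at each scale the outline contour is traced and the number of
  curvature sign reversals along it is counted, with curvature estimated
  by symmetric finite differences at a 15-pixel gap,
  $k = (x' y'' - x'' y') / (x'^2 + y'^2)^{3/2}$. Reversal counts summed
  over views, one per scale, form the descriptor: a smooth boundary
  yields zeros, a spiculated one a positive, scale-decaying profile.
* **Spherical-harmonic reconstruction error (SPHARM).** The mask's
  iso-surface is triangulated (marching tetrahedra on a mildly smoothed
  indicator), mapped to the unit sphere by an attraction–repulsion
  relaxation, and the three coordinate functions are expanded in real
  spherical harmonics by iterative residual fitting (order $l$ fitted by
  least squares to the residual of orders $< l$). The descriptor is the
  normalized RMS reconstruction error after each order $1..70$: simple
  shapes collapse within a few orders, complex shapes keep residual
  error much longer.
* **Geometric features.** Volume, convex volume, equivalent diameter,
  surface area, solidity, principal axis length and extent of the mask
  (7 values).

Classification: each descriptor feeds a stacked autoencoder with three
hidden layers, each reducing its input by one third
($\lceil 2d/3 \rceil$), greedily pretrained on reconstruction and
fine-tuned with a two-class softmax, producing a malignancy
probability. A second network (one hidden autoencoder of width 4 plus
softmax) fuses the six probabilities into the final diagnosis. Data are
split 70/30 with stratification; metrics are accuracy, sensitivity,
specificity, precision (percent) and trapezoidal ROC AUC.

# The phantom generator — what it emulates and what it does not

Real annotated CT cohorts cannot ship with a package, so every claim is
exercised on synthetic nodule phantoms that reproduce the contrasts the
descriptors target, inside the same 40 mm / 1 mm-isotropic VOI:

* **Benign**: a volume-preserving near-sphere (axis distortions ≤ 8%),
  interior $-50$ HU plus mildly correlated noise (correlation length
  0.8 mm, SD 15–25 HU), background $-850$ HU. The mild correlation
  mimics the smoothness real CT texture gets from partial volume and
  the reconstruction kernel; it also matters statistically — a
  Markov–Gibbs field trained on perfectly white texture would have
  nothing to learn (its empirical co-occurrences equal the independent
  reference by construction), leaving the energy feature blind.
* **Malignant**: a radial surface
  $r(u) = R\,(1 + a\,[\mathrm{spikes}(u) + 1.8\,\mathrm{lobes}(u)])$
  with 6–12 narrow von Mises–Fisher spikes (concentration 50, relative
  amplitude $a = 0.3$–$0.5$) on 6 wide zero-mean lobes (concentration
  8), plus interior texture from Gaussian-smoothed white noise
  (correlation length 2–4 mm) rescaled to an in-mask SD of 50–90 HU.

Design notes, fixed once:

* Spikes are smooth bumps rather than hard cones so the curvature
  scale-space sweep sees graded reversals across scales. Spike centres
  are a Fibonacci-sphere arrangement under a random rotation — random
  in orientation yet guaranteed separated, so `spikeCount` spikes
  produce `spikeCount` boundary lobes.
* The lobulation term exists because narrow spikes barely move the
  convex hull: without lobes the solidity of a spiculated mask stays
  near 0.96 no matter how sharp the spikes, which would leave the
  generator unable to produce the benign/malignant solidity contrast it
  promises (benign ≥ 0.95, malignant ≤ 0.90 at spike amplitude ≥ 0.3).
  Lobulation is also what radiologists actually see in malignant
  nodules alongside spiculation.
* The malignant texture field is rescaled to its target SD *inside the
  mask*: a correlated field has less local than global variance, and
  the contract is about the nodule interior. The default malignant SD
  (70 HU) is 3.5 times the benign default (20 HU), keeping the
  "at least 3 times noisier" property comfortably true rather than
  knife-edged.
* HU levels (−50 nodule / −850 background) are arbitrary but fixed.

Phantoms are deterministic given their seed; cohorts derive per-record
seeds from a master seed. What the phantoms do **not** model: vessels
and pleural attachments, partial-volume and reconstruction-kernel
effects, CT noise spectra, and the labelling noise of human readers.
Passing tests on phantoms therefore demonstrates the machinery —
descriptor contracts, invariances, learnability of a clean contrast —
not clinical performance.

# Numerical choices

* **Coordinates.** Voxel indices are 1-based in R; physical position =
  origin + (index − 1) · spacing; volumes are treated as axis-aligned.
  VOI extraction and resampling use trilinear interpolation (bilinear in
  2D views), with −1000 HU (air) padding outside the parent volume.
  Trilinear weights are renormalized on locally constant cells so a
  constant volume resamples exactly.
* **Views.** 2D views form a pencil of planes sharing the scanner z
  axis, rotated by $k \cdot 180^\circ / V$ (antipodal planes coincide).
  ALBP restricts code pixels to the nodule cross-section eroded by
  $R_{\max} + 1$ pixels, so every sampled neighbourhood lies inside the
  nodule: on a constant-intensity nodule every code is then exactly
  $2^{R_{\max}} - 1$, as the flat-field contract requires. The
  comparisons $f(x) \ge 0$ carry a $10^{-9}$ relative tolerance so the
  flat-field case survives interpolation round-off.
* **HOG.** Central differences (one-sided at faces); the VOI is padded
  with edge values to $45^3$ so that $5^3$ blocks tile into $3^3$-voxel
  cells. The nearest-3-axes constraint is enforced explicitly: plain
  threshold subtraction leaves up to five positive components for
  directions near dodecahedron face centres, so the vote keeps only the
  three largest. A zero gradient casts no vote; block normalization
  carries an $\epsilon = 10^{-12}$ guard.
* **PSCSS.** Sections are taken at 0.25 mm in-plane pixels — the gap
  (15 px) and scale grid are pixel quantities and presume sub-millimetre
  pixels; at 1 mm sampling a typical phantom contour is shorter than
  two gaps. The binary mask is pre-smoothed with a 0.7-voxel 3D
  Gaussian and sectioned as continuous values (contoured at 0.5):
  without this, voxel staircase flicker dominates the reversal counts
  at the finest scales. Contours are resampled to unit-pixel arc steps
  and oriented counter-clockwise; zero-curvature points carry the
  previous sign. The outline at each scale is the 0.5 iso-level of the
  Gaussian-smoothed section, which is where an edge detector localizes
  a smoothed binary boundary, and which arrives already traced and
  ordered.
* **SPHARM.** Marching tetrahedra (six path tetrahedra per cube, edge
  vertices deduplicated) give a watertight, outward-oriented surface;
  the 0.7-voxel pre-smoothing removes staircase bias from areas and
  curvatures (masks under 27 voxels are meshed unsmoothed so they are
  not erased). The attraction–repulsion relaxation projects each
  update onto the tangent plane — a symmetric spherical mesh is then a
  true fixed point — with gentle weights (attraction 0.3, repulsion
  0.01, inverse-square with a cutoff of twice the mean edge length, cap
  100 iterations, tolerance $10^{-6}$). Stronger settings (0.5/0.1,
  500 iterations) were tried first and rejected: the repulsion term
  jitters the parametrization at the mesh scale and inflates the
  order-1 reconstruction error of a near-sphere from 0.02 to 0.11,
  destroying the complexity ordering the descriptor exists to measure.
  The reconstruction error is the RMS (not mean) Euclidean vertex
  distance divided by the mean radius: nested least squares guarantees
  a non-increasing curve for RMS.
* **MGRF.** The centred-frequency potentials make the model fully
  explicit and deterministic; the partition function is never needed
  because only energies are used. Pairwise tables are symmetrized so
  each family is invariant under offset negation.
* **Classifier.** Min-max feature scaling to $[0,1]$ on training
  ranges (constant columns map to 0.5); Glorot-uniform initialization;
  full-batch Adam at learning rate 0.01; 100 pretraining plus 100
  fine-tuning epochs (training plateaus well before; doubling the
  epochs changes no reported metric but doubles the cost of the
  2500-input stack). Everything is seeded and bit-reproducible.

# Open design points and how they were resolved

* The view-plane family for "equally distributed" views is not uniquely
  determined; a z-axis pencil is used, shared by ALBP and PSCSS.
* Multi-view ALBP histograms are concatenated, not summed, preserving
  per-view information.
* Population (divide-by-$n$) SD in the ALBP statistics.
* The half-binning HOG variant folds antipodal vertex pairs; the
  tetrahedron has no antipodal pairs, so it supports full binning only.
* The PSCSS scale grid $\{1, 2, 4, 8, 16\}$ px and the Canny hysteresis
  question are resolved by the iso-contour formulation above;
  "aggregated" is read as a sum over views.
* The 7-voxel star clique stands in for the higher-order clique
  geometry of the wider MGRF literature; its configuration statistic
  (matching-neighbour count) keeps the potential table finite and
  hand-checkable.
* "Reduces the dimensionality by one third" is read as output =
  two-thirds of input; the alternative (retain one third) can be
  configured through explicit layer widths.

# Problem sizes used by the shipped experiments

The end-to-end benchmark generates 200 phantoms (100 per class), splits
them 140/60 with stratification, trains the MGRF on the benign training
nodules and all seven networks on the training split, and reports
test-set metrics; on one CPU this takes roughly ten minutes, dominated
by descriptor extraction and the 2500-input autoencoder stack. Property
tests use 10–50 phantoms per claim.

# Known limitations

* The rotation stability of the PSCSS descriptor is limited by count
  quantization: with 5 views the descriptor sums on the order of a
  hundred discrete reversal events, so two poses of the same phantom
  differ by roughly 10–13% in L1 on average. More views would reduce
  this, but 5 views is the descriptor's operating point.
* SPHARM error floors (~0.02–0.04 normalized) reflect 1 mm
  digitization of the masks, not the harmonics themselves; an exact
  unit-sphere triangulation reconstructs to numerical precision by
  order 2.
* HOG separates the phantom classes poorly on its own (the phantom
  contrast lives in texture variance and boundary shape, not in
  oriented-gradient statistics); fusion is unaffected because the
  other five descriptors carry the signal.
* The DICOM reader handles uncompressed explicit-VR little-endian
  series only; anything else should be converted to NIfTI first.
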