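---
title: "Nonlinear latent representations of developmental surface fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear latent representations of developmental surface fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Resting-state fMRI of the fetal and neonatal brain is conventionally analysed
with linear decompositions (group spatial ICA, anatomical parcellations): a
cortical activity frame `x` (one value per surface vertex) is expressed as
`x ~ A y`, with `A` a fixed spatial basis and `y` low-dimensional
coefficients. The developing brain changes so rapidly that a fixed linear
basis can be a poor summary. This package implements the alternative studied
in recent developmental-connectomics work: a beta variational autoencoder
(beta-VAE) whose convolutional encoder compresses each activity frame into
256 latent variables and whose decoder maps latent vectors back to cortical
patterns, trained with the loss

    L = || x - x' ||^2  +  beta * KL( N(mu_z, sigma_z) || N(0, I) )

where `x'` is the reconstruction and the KL term pulls the per-frame
posterior towards an isotropic prior. Downstream analyses all operate on the
encoder's posterior means `mu_z`:

* **Reconstruction quality** — per-frame Pearson correlation between original
  and reconstructed cortical pattern ("reconstruction degree"), aggregated on
  the Fisher-z scale, compared against linear bases of rank 30-300, and
  profiled against explicitly smoothed copies of the data to estimate a
  model's implicit smoothing FWHM.
* **Brain-age prediction** — latent functional connectivity (the covariance
  of every latent pair; `L*(L-1)/2` features) feeds a linear support-vector
  regression of postmenstrual age, with feature selection strictly inside
  training folds, affine prediction-bias adjustment on a validation split,
  and a single-feature (global network strength) transfer variant for
  cross-acquisition prediction.
* **Network mapping** — temporal ICA (extended Infomax) on latent timecourses
  concatenated across subjects yields independent latent bases; each basis is
  projected to the cortex by decoding randomly scaled copies of it and taking
  the per-vertex covariance with the scale factor (a Monte-Carlo
  linearization of the decoder that is exact for a linear decoder).
* **Group contrasts** — per-subject component-timecourse variances are
  correlated with age (BH-FDR across components), and age-group network maps
  are built by dual regression with the group difference formed in latent
  space before decoding.

Because convolutions need a regular grid, cortical data are first rearranged
by *geometric reformatting*: each hemisphere's vertices are assigned
injectively to cells of a 2-D grid (Lambert azimuthal equal-area projection
of the spherical coordinates followed by a deterministic greedy
nearest-free-cell assignment). Injectivity makes the forward/inverse pair
exactly invertible on assigned vertices, so reformatting never limits
reconstruction fidelity; medial-wall vertices are excluded from analysis
masks. The original published pipeline defers its reformatting layout to a
prior code release; this package deliberately defines its own provably
invertible scheme, since every downstream quantity depends only on having a
faithful, invertible rearrangement.

## The synthetic cohort and what it does (not) show

Real neonatal cohorts of this kind are restricted-access, so the package
ships a fully specified generator used by all tests:

* a two-hemisphere icosphere mesh (radius 60 mm; the right hemisphere a
  mirrored copy; 5% of vertices around each inner pole flagged as medial
  wall);
* `K = 5` ground-truth networks: geodesically smoothed (15 mm FWHM)
  orthonormalized Gaussian random fields;
* independent network sources with unit-variance Laplace AR(1) innovations
  (autocorrelation 0.3). Super-Gaussian sources are the standard temporal-ICA
  assumption for burst-like network activity and make the sources
  identifiable; Gaussian sources would not be.
* age acts on the **source variances**: subject age is uniform on 24.29-44.87
  postmenstrual weeks and source `k` has variance
  `1 + gamma_k (age - 34.58)` with
  `gamma = (0.05, -0.03, 0.07, 0, 0.02)` per week. This one mechanism drives
  both latent-FC age prediction and the component-variance-versus-age
  analysis, mirroring how the paper's cohort expresses age in connectivity.
* noise has two parts: spatially structured noise (white noise smoothed at
  25 mm FWHM, sd 0.8) — physiological BOLD noise is spatially broad, which
  gives the realistic smoothly decaying spatial noise eigen-spectrum — plus
  white thermal noise (sd 0.6; doubled in the `dbi_like` profile). A
  per-subject lognormal SNR jitter (sd 0.15) gives subjects distinct data
  quality;
* acquisition profiles `dhcp_like` (T = 1400 frames, TR = 0.392 s) and
  `dbi_like` (T = 150, TR = 2 s, noisier) emulate the two centres' scanner
  differences; a `desk` profile (T = 150, TR = 0.72 s) is used for
  simulation studies.

Everything is reproducible from `(seed, parameters)` and the generator
returns a manifest of all draws. The generator emulates *linear* mixtures of
smooth networks with age-dependent variances; it does not emulate
hemodynamic nonlinearity, motion artifact structure, or registration error.
Passing tests therefore demonstrate that the pipeline's machinery recovers
known structure under its own assumptions, not that the scientific claims
hold on real data.

The effect sizes above were chosen once so that desk-scale age prediction has
a chance-normalized error around 0.5; they are recorded in the generator
defaults and are not tuned per analysis.

## Numerical and design choices

* **Variance conventions.** Vertex standardization uses the population
  variance (divide by T). FC uses the sample covariance. ICC is the two-way
  random-effects single-measure ICC(2,1); no variant was named upstream, and
  (2,1) is the standard test-retest choice.
* **Bandpass.** Zero-phase forward-backward order-4 Butterworth; the
  0.01-0.1 Hz default is the usual resting-state band.
* **Geodesics.** Edge-graph shortest paths stand in for exact geodesics.
  Smoothing kernels are truncated at 3.5 sd and row-normalized, so constants
  are preserved exactly. On the subdivision-3 desk mesh (7.9 mm edges),
  kernels under ~6 mm are below the mesh resolution and act as the identity;
  all FWHM-sweep analyses therefore use the subdivision-4 mesh (4 mm edges),
  where the 1-10 mm grid is resolved.
* **VAE architecture.** Five stride-2 kernel-4 convolutions (channels
  32-64-128-256-256 at full scale), leaky-ReLU (slope 0.2), dense heads for
  `mu` and log-variance (clamped to [-8, 4]), mirrored decoder with a linear
  output layer, validity-masked reconstruction loss. Transposed convolutions
  use He-style initialization with the effective fan-in `(k/stride)^2 * C`.
  The published hyperparameters (256 latents, beta = 9, lr 1e-4, batch 128)
  are the package defaults.
* **Training at desk scale.** The KL term acts per frame while reconstruction
  scales with the number of grid cells, so the KL pressure equivalent to
  beta = 9 on 38,864-cell frames is `9 * 1218/38864 ~ 0.3` on the 2,048-cell
  desk grids; desk-scale studies use beta = 0.3, batch 32, lr 6e-3, a KL
  warm-up over the first quarter of epochs (the standard guard against
  posterior collapse) and global gradient-norm spike clipping. Test-scale
  problem sizes are a 14-subject x 160-frame cohort (2,000 training frames,
  20 epochs, 64 latents at channels 16-32-64-64-64) and a 300-subject
  cohort at T = 150 for prediction studies.
* **Deterministic seeding.** Initialization, shuffling, reparameterization
  sampling, ICA initialization and Monte-Carlo scale factors are all governed
  by explicit seeds; checkpoints restore encodings bit-exactly.
* **ICA.** Spatial ICA (linear baseline) is FastICA with deflation and tanh
  contrast after PCA whitening; temporal ICA is extended Infomax (natural
  gradient, data-size-adapted blocks, annealed step size, kurtosis-sign
  switching) with unit-variance components ordered by explained latent
  variance. Components are defined up to permutation and sign; matching
  across groups is greedy on |Pearson r| (an exhaustive optimal assignment is
  available for k <= 8), and map signs are fixed so the strongest vertex is
  positive.
* **Degenerate inputs.** Constant frames yield NA reconstruction degrees
  (dropped, with a warning, rather than zero-filled); constant features are
  excluded from selection; a variable fully explained by covariates returns
  partial r = 0; equal session ages collapse to a single covariate in the
  inter-session analysis.
* **Indexing.** All vertex, frame and component indices are 1-based, the R
  convention.

## Known limitations

* A from-scratch VAE trained for a 20-epoch desk-scale smoke budget (~1,300
  Adam steps) acquires eigendimensions of the data in eigenvalue order and
  reliably learns the strong network dimensions but not the weak
  structured-noise dimensions; an exact rank-30 SVD-subspace baseline can
  therefore out-reconstruct it on held-out frames at this training scale. The published comparison rests on a VAE pretrained to
  convergence on a large adult corpus — orders of magnitude more optimization
  than a smoke train. The acceptance suite states this comparison as the
  test it is, and it is expected to fail at desk scale; the quantitative
  analysis is in the repository notes.
* CIFTI-2 dense timeseries are not parsed (the format needs a NIfTI-2 reader
  plus the BrainModel XML extension); GIFTI `.func.gii` and the package's
  internal container are the supported on-disk formats.
* Geodesic distances are graph shortest paths, which overestimate true
  geodesics by a few percent on coarse meshes.
* The Monte-Carlo decoder projection is a linearization; for a strongly
  nonlinear decoder the map is an approximation whose quality is checked
  only through its convergence and linear-decoder oracles.

## Reproducing the numbers

The package's testthat suite regenerates every synthetic cohort and model it
needs at run time (no stored fixtures) and `scripts/acceptance.R` recomputes
the reformatting-fidelity quantity from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
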