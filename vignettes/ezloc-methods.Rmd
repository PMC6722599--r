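---
title: "Localizing the epileptogenic zone from ictal SPECT and EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the epileptogenic zone from ictal SPECT and EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezloc)
```

## The problem

In drug-resistant epilepsy with no visible MRI lesion, surgery hinges on
localizing the epileptogenic zone (EZ) — the tissue whose removal stops
the seizures — from noninvasive functional data. Two modalities carry
complementary information. Ictal perfusion SPECT captures the blood-flow
surge at the seizure focus: subtracting an interictal scan from an ictal
scan, after co-registration and intensity normalization, highlights
hyperperfusion (the SISCOM technique). Scalp EEG recorded during the
seizure can be inverted into an estimate of the cortical current sources
(EEG source imaging, ESI), but the inverse problem is underdetermined and
needs spatial priors. This package implements both, and their fusion: the
SISCOM hyperperfusion clusters are injected as additional spatial priors
into the EEG inverse solution, on the physiological premise that the
synaptic currents generating the scalp EEG also impose a metabolic demand
visible as focal hyperperfusion.

Every analysis yields three EZ hypotheses on the MRI grid — the SISCOM
cluster mask, the ictal-ESI map, and the ictal-ESI-with-SISCOM-prior map —
plus, when a postsurgical resection mask is available, a voxelwise
coincidence table (sensitivity and specificity of each hypothesis against
the resection).

## SISCOM

The pipeline follows the classical subtraction methodology, in this fixed
order: rigid co-registration of the interictal scan to the ictal scan
(mutual-information maximization), brain masking, normalization of each
scan to a common global brain mean, voxelwise subtraction, 3-D Gaussian
smoothing of the difference image, z-scoring, co-registration to the MRI,
and suprathreshold cluster extraction.

Parameters that matter:

* **Smoothing FWHM, 12 mm** (default). The kernel standard deviation per
  axis is `FWHM / (2 sqrt(2 ln 2)) / voxel_size`, honoring anisotropic
  voxels; the kernel is unit-sum so interior image mass is preserved.
* **z threshold, 2.0** (default), treated as the cluster-forming
  threshold. The z-score uses the mean and *population* SD over all brain
  voxels, a deliberate convention so that toy examples (two voxels valued
  1 and 3 give z = -1, +1) are exact; with tens of thousands of brain
  voxels the sample/population distinction is immaterial.
* **Normalization target, brain mean = 100.** Any positive constant is
  equivalent after z-scoring; 100 matches common SPECT practice and eases
  visual inspection.
* **Cluster connectivity 26, minimum size 10 voxels** (configurable; the
  literature states neither).
* **Two-threshold reporting.** Cluster extent is defined at z >= 2, but
  the full methodology reports as hyperperfusion *foci* only clusters
  whose peak reaches z >= 4 (configurable) — the usual peak/extent split
  for statistical maps. Inter-session perfusion variability produces
  diffuse clusters that barely exceed the forming threshold; in the
  synthetic world true foci peak at z 5.5-7.5 while variability clusters
  stay below about 3.3, so the criterion separates them cleanly and
  preserves SISCOM's near-perfect specificity.

Degenerate inputs fail loudly: identical scans produce a zero-SD
difference and raise an error rather than dividing by zero; flat
(single-intensity) images cannot be registered.

## Registration

Rigid 6-DOF registration maximizes the mutual information of the joint
intensity histogram (64 bins) over voxels where both images are nonzero.
The optimizer is a derivative-free Nelder-Mead simplex run over a
block-mean pyramid (factors 4, 2, 1), with one simplex restart per level
— restarts re-inflate collapsed simplices and measurably improve the
rotational optimum. Both images are pre-smoothed (10 mm FWHM by default)
before optimization: for noisy emission images this is standard practice
and sharpens the MI optimum; on noisy phantoms it reduces worst-case
rotation errors from several degrees to well under one.

The returned transform maps fixed-space world coordinates to moving-space
world coordinates, so `resample_to(moving, fixed, tf)` aligns the moving
image; transforms serialize as plain-text 4x4 matrices.

## Forward model

The required forward model is the analytic three-shell concentric sphere
(brain, skull, scalp; default radii 79/82/88 mm and conductivities
0.33/0.0042/0.33 S/m — standard literature values, configurable). The
spherical-harmonic series is evaluated with transfer coefficients
propagated across shells by an analytic 2x2 map per harmonic order, which
stays numerically stable to high order; the series is truncated adaptively
(worst-case remainder below 1e-12 relative). In the equal-conductivity
limit the solver agrees with an independently derived closed form
(generating-function summation of the single-sphere series) to better
than 1e-12 relative — the package's primary forward-model oracle.

Dipoles are fixed-orientation (surface normals), one per source vertex;
gains are average-referenced by construction and declared in microvolts
per nA*m. An optional boundary-element tier (centroid collocation,
analytic solid angles, deflation of the constant nullspace) exists for
non-spherical geometry; on spherical meshes at icosphere level 3 its
median relative difference measure (RDM) against the analytic solution is
about 0.02, and decreases with mesh refinement.

## The inverse solution

The sensor covariance is modeled as a nonnegative mixture

> C = lambda_0 I + sum_i lambda_i (L q_i)(L q_i)'

with one rank-one component per spatial prior profile `q_i`. Component
weights are optimized by restricted maximum likelihood (ReML) ascent on
the variational free energy over log-hyperparameters, using Fisher
scoring with step-halving so every accepted step increases the objective
(the free-energy trace is non-decreasing by construction). A sparse
hyperprior shrinks components toward a negligible weight; components
falling below 1e-8 of the largest are pruned — automatic relevance
determination (ARD). Posterior mean currents follow from the standard
Gaussian posterior under the optimized prior.

Design choices worth knowing:

* **Patch library.** 256 patch components by default, each a truncated
  graph-diffusion kernel (three half-lazy random-walk steps, roughly an
  8 mm effective radius on the test spheres), peak-normalized. Patch
  centers are spread by deterministic farthest-point sampling rather than
  uniform random draws: random subsets of a 642-vertex sphere leave
  2-ring coverage holes that systematically bias peak localization, while
  even spacing matches how sparse-patch libraries are built in practice.
  The seed only selects the first center.
* **Component scaling.** Each component's sensor field is normalized to
  unit average variance so all hyperparameters share a scale; the
  normalization is undone when posterior currents are assembled.
* **Short epochs.** The data second-moment matrix is shrunk 5% toward its
  diagonal when T < 4M (ictal windows are short).
* **SISCOM priors augment, never replace.** Each suprathreshold cluster
  contributes one component: every cluster voxel maps to its nearest
  source vertex within 10 mm (deeper clusters are skipped with a
  warning), and the component is the count-weighted sum of one diffusion
  kernel per voxel — so the component is centered on the cluster's mass,
  not on an arbitrary seeded vertex set. SISCOM components enter with the
  same initial hyperparameter as patches; the data decide their weight.
  With an empty cluster set the informed inversion is bit-identical to
  the plain one.

## EZ binarization

Per-vertex power is the time-mean squared posterior current; vertices at
or above a fraction (default 0.5) of the maximum are selected and
rendered to the MRI grid by marking voxels within a rendering radius of a
selected vertex. The rendering radius defaults to 15 mm: the binarized map
stands for the resection hypothesis the coincidence analysis evaluates, so
a single-patch estimate should render a volume commensurate with a small
cortical resection rather than a thin shell. Both parameters are
configurable; results report them.

## The synthetic world

No patient data ship with the package; a generator produces complete
ground-truth bundles. What it emulates, and what it does not:

* **Phantom head** (64^3 voxels at 2 mm): spherical brain (55 mm) inside
  a head shell (62 mm), with a smooth baseline perfusion field,
  ventricle-like low-uptake ellipsoids, a cerebellum-like region and a
  mild left/right asymmetry. The internal structure is what makes
  rotations identifiable to the registration module, as in real scans.
  The default grid cannot hold adult-head shell radii, so the bundle head
  model is geometrically scaled (cortex sphere 48 mm, shells 55/58/62 mm);
  the physics is scale-consistent.
* **SPECT pair**: interictal = baseline x session field x (1 + noise);
  ictal additionally carries a multiplicative (1 + 0.20) factor inside an
  8 mm hyperperfusion blob. Three noise/realism components matter. The
  baseline is blurred by an 8 mm Gaussian system PSF (sharp emission
  edges are unphysical and would leave edge artifacts after registration
  resampling); the PSF precedes the blob factor, so the implanted
  ictal/interictal ratio stays exactly 1.20. Voxelwise Gaussian noise
  (SD 5% of the local mean) proxies post-reconstruction Poisson noise.
  Each scan is also modulated by an independent smooth (25 mm)
  inter-session perfusion variability field of 1.5% relative SD: this is
  the variance component that survives the 12-mm smoothing and therefore
  sets the z-score denominator, exactly as test-retest perfusion
  variability does in real subtraction imaging. Its amplitude is
  calibrated to the single prescribed recovery point (top-cluster Dice of
  at least 0.6 against the true blob at the default blob and noise
  settings); with iid noise alone the suprathreshold footprint balloons
  to several times the blob. An optional rigid misregistration is applied
  to the ictal scan.
* **EEG**: active cortical patches (diffusion-kernel profile, damped 6 Hz
  oscillation, 10 nA*m, 1 s at 200 Hz) projected through the three-shell
  leadfield with white sensor noise at 15 dB channel-averaged SNR by
  default. Real ictal EEG morphology (spike-wave complexes, propagation,
  artifacts) is not emulated; a green test establishes correct inverse
  behavior for focal oscillatory sources, not robustness to clinical
  artifact.
* **Scenarios.** `focal` colocalizes blob and source and emits an 18 mm
  resection sphere over the focus — resections exceed the perfusion
  focus, which is why the blob (8 mm) is deliberately smaller.
  `discordant` reproduces the failed-surgery phenomenology: the blob sits
  30 mm posterior to the source and the resection 30 mm anterior, so all
  three EZ estimates fall largely outside the resection and sensitivities
  stay low. `multifocal` activates two foci (right frontal, left
  temporal), placed on prior-library patch centers and scaled to equal
  scalp power so both are equally representable — without this the
  fraction-of-max threshold sits exactly at its 0.5 boundary for the
  second focus and the two-component outcome becomes a coin flip.

Under this stated world the qualitative clinical pattern reproduces: the
combined (ESI + SISCOM prior) estimate attains the highest sensitivity
and SISCOM the highest specificity in at least 8 of 10 paired focal
bundles, with typical sensitivities around 20-40% (SISCOM, a confined
focus inside a larger resection), ~82% (ESI) and 82-97% (combined), and
SISCOM specificity at or near 100% — the ordering reported for
favorable-outcome patients in the motivating clinical series.

## Numerical conventions

* World frame RAS millimetres; voxel indices 0-based in the affine
  convention; grid equality tolerated to 1e-4 mm.
* Resampling is pull-style trilinear; out-of-field voxels become 0 (not
  NaN) so downstream arithmetic stays defined.
* NIfTI-1 I/O is implemented in base R (no NIfTI package exists in the
  supported dependency set) and validated against an independent reader;
  integer data round-trip bit-exactly.
* Ties in the EZ argmax are kept in deterministic vertex-index order; the
  voxel-to-vertex mapping breaks distance ties by first index.
* All stochastic steps (phantom fields, noise draws, patch-center choice)
  are seeded; bundle manifests record seeds and md5 checksums, and
  re-running with the manifest's seed reproduces the checksums.

## Known limitations

* The spherical head model and scaled phantom geometry test the
  machinery, not anatomical realism; no segmentation of real T1 images is
  attempted.
* The BEM tier is validated on spherical meshes only, and mesh
  resolutions beyond icosphere level 3 become memory-hungry
  (dense collocation matrices).
* EDF and GIfTI readers are not included; EEG enters as a plain TSV
  matrix and surfaces as OFF/OBJ.
* Sensitivity/specificity are reported without confidence intervals, and
  the evaluation region defaults to the whole brain mask — both stated in
  every result, since the choice of region changes specificity
  materially.
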