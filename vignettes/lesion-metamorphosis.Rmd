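---
title: "Phase-based lesion metamorphosis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based lesion metamorphosis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemorph)
```

## The problem

An ischemic stroke lesion visible on diffusion-weighted imaging (DWI)
changes shape and extent over days to weeks: parts of the boundary advance
into previously healthy-appearing tissue (expansion) while other parts
recede (contraction). Whether those local dynamics are driven by the local
perfusion state is a central question in stroke imaging. This package
quantifies the dynamics with a metamorphosis registration between
timepoints, and relates the most dynamic lesion areas to relative
mean-transit-time (rMTT) perfusion values.

The analysis runs in two phases per case — acute DWI to subacute DWI, then
subacute DWI to the final (≥ 1 month) lesion — because acute and subacute
perfusion carry different clinical information. The second phase runs only
when a subacute MTT map exists; its absence is recorded explicitly, never
skipped silently.

## Metamorphosis model

A plain diffeomorphic registration cannot create or destroy intensity, but
a growing lesion does exactly that: new hyperintense tissue appears.
Metamorphosis couples a geometric path (a flow of diffeomorphisms
$\phi_t$ generated by velocity fields $v_t$ via
$\dot\phi_t = v_t(\phi_t)$, $\phi_0 = \mathrm{id}$) with a photometric
path (pointwise intensity change). Discretely, the path is $T+1$ intensity
frames $I_0 \dots I_T$ and $T$ piecewise-constant velocity fields, and the
estimate minimizes

$$U(I, v) = \sum_t |v_t|^2_V \,\Delta t
  + \frac{1}{\sigma^2} \sum_t
    \Big\lVert \frac{I_{t+1} - I_t}{\Delta t} + \nabla I_t \cdot v_t
    \Big\rVert^2_{L^2} \,\Delta t .$$

The second integrand is the residual of the advection equation: intensity
change that transport does not explain, i.e. true photometric change. All
$L^2$ norms carry the voxel-volume weight so energies are comparable
across grid resolutions.

**Exact observation matching.** The observed images are fixed path knots:
$I_0$ and $I_T$ (and any intermediate observation) are held fixed while
the interior frames and all velocities are optimized. This realizes the
model property that the path fits every observation exactly, reports an
endpoint residual of numerically zero, and decouples a multi-observation
problem into independent two-image segments whose flows are concatenated
continuously. We chose this over penalized (inexact) endpoint matching
with an annealing schedule: it removes two tuning constants, and the
quantity the rest of the pipeline consumes — the velocity path — is the
same object in both formulations.

**V-norm.** $|v|^2_V = \langle m, K m\rangle$ with $v = K m$, where $K$ is
a Gaussian kernel applied as a periodic (FFT) convolution with transfer
function $\exp(-2\pi^2\sigma_K^2\nu^2)$ — strictly positive, hence $K$ is
symmetric positive definite and the norm well defined. The kernel width
(`kernelWidth`, mm) is the spatial scale of credible deformation: small
widths localize motion at intensity edges; widths comparable to the lesion
radius make the recovered flow nearly rigid across it. The package default
is 4 mm, a typical lesion-boundary scale.

**Optimizer.** Alternating steepest descent: one backtracking gradient
step on all momenta (intensities fixed), then one on the interior
intensity frames (velocities fixed); each accepted iterate must not
increase $U$, and a velocity step whose integrated flow folds the grid
(min Jacobian determinant ≤ 0) is rejected with the step size halved.
Initialization is the pure-photometric path ($v=0$, linear intensity
interpolation). Iteration stops when the relative energy decrease falls
below `tol` (default $10^{-6}$) or at `maxIters` (default 500); hitting
the cap returns the best path with `converged = FALSE`, never silently.
Interpolation is multilinear with boundary clamping; 2D grids are
first-class so tests and experiments run quickly, and all operators are
dimension-generic up to 3D.

### Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `sigma` | — | 0.1 | smoothness/fidelity trade-off; large values suppress deformation entirely |
| `kernelWidth` | mm | 4 | spatial scale of the V-norm kernel |
| `nTimesteps` | — | 10 | discrete steps per path segment |
| `maxIters` | — | 500 | optimizer cap |
| `stepSize` | — | 0.5 | initial backtracking step |
| `tol` | — | 1e-6 | relative energy-decrease stop |
| `endpointTol` | intensity | 1e-2 | maximum accepted observation residual (structurally 0 here) |

## Deformation maps and the threshold rule

The total deformation map over the phase-start lesion mask is the
time-integrated squared speed $\sum_t \lVert v_t(x)\rVert^2 \Delta t$
(mm² per unit path time). A squared sum is non-negative, so the direction
is assigned separately: the sign at a voxel is the sign of the
time-averaged projection of $v_t$ onto the outward normal of the lesion
boundary, taken as the gradient of the signed Euclidean distance to the
mask (smoothed by one voxel, because raw distance-transform normals are
axis-quantized on rasterized masks). Projections below a dead-band
($10^{-6}$ mm per unit time) are left unsigned. The map covers all voxels
of the lesion mask; a boundary-shell-only mode (mask minus its erosion) is
available by flag since the alternative reading — only a boundary band —
cannot be excluded.

Highly dynamic regions use a mean ± sd rule on *speed* (the square root of
the map, mm per unit time): contracting voxels above the contraction
mean − sd, expanding voxels above the expansion mean + sd, strict
inequalities. The printed form of this rule references the *contraction*
statistics for both directions, which is internally inconsistent for
expansion; the package defaults to each direction's own statistics
(`rule = "corrected"`) and ships the literal variant
(`rule = "as-printed"`) behind the same interface, so both readings are
reproducible. The rule is scale-equivariant: rescaling all velocities
changes thresholds but not masks.

Deformation magnitudes are reported per normalized path time; a phase
duration in hours can be used to rescale them to mm/h-style units
externally.

## rMTT and the Gaussian fits

The rMTT map divides each lesion voxel's MTT by the mean MTT over the
mirror-reflected lesion region in the opposite hemisphere. The reflection
plane defaults to the central sagittal index $(n+1)/2$ (images are assumed
midsagittally aligned); with that default the reflection is an exact
involution. Non-finite or non-positive mirrored voxels are excluded from
the normalizer and counted.

Mean deformation speed is then computed per rMTT bin (default width 0.01,
configurable — rMTT ratios typically span ~0.1–3) separately for
contracting and expanding voxels, and a Gaussian
$a\,e^{-(x-\mu)^2/2s^2}$ is fitted to the binned means by
Levenberg–Marquardt least squares (`minpack.lm`), initialized from the
moments of the binned curve. The fit is unweighted over bins by default —
one mean-deformation point per rMTT value — with a count-weighted variant
by flag; whether the original analysis used raw voxel pairs or binned
means is not determinable, and binning makes the fit insensitive to voxel
order by construction. RMSE is the root mean squared residual over bins
(exactly 0 for an exactly Gaussian relation). The reported interval
$[p_1, p_2] = [\mu - s, \mu + s]$ is stored ordered; we deliberately never
label its ends "upper"/"lower" because the two published descriptions of
that labelling contradict each other.

## Synthetic data: what it emulates, and what it does not

`generateCase()` builds: a two-hemisphere elliptical phantom symmetric
about the central sagittal plane (so contralateral mirroring is exact by
construction); 1+ spherical lesion components with independent signed
radial growth per phase ("multi-component" means ≥ 2 disconnected
components); images in [0, 1] with additive Gaussian noise (sd 0.01 by
default, clipped); an MTT map at a healthy baseline of 6 s with an
assignment region around each moving component boundary. Ground truth
comprises the expansion/contraction masks (exact set differences of the
rasterized masks) and an approximate radial displacement field.

The default conditions are two components on a 64×64 grid (1 mm voxels),
one growing by +2 voxels and one shrinking by −2 in phase 1 (±1 in
phase 2) — chosen as a minimal case that exercises both deformation
directions at realistic lesion scales.

**The configured rMTT structure.** In a zone around each moving boundary,
assigned rMTT deviates from the configured mean $\mu$ in proportion to the
voxel's radial distance from the phase-start boundary (capped at 2.5
configured-sd, with a random balanced sign): voxels expected to deform
most carry rMTT $\approx \mu$, and the binned deformation-vs-rMTT relation
is symmetric about $\mu$ by construction. This is what makes the
end-to-end recovery test meaningful: the pipeline must register the
images, sign the deformation correctly, normalize MTT contralaterally and
fit the peak — an error anywhere shifts the recovered $\mu$. Defaults put
contraction at $\mu_c = 1.5$ and expansion at $\mu_e = 0.8$ (sd 0.1),
separated by more than 3 sd so correctly analyzed cases give disjoint
$[p_1, p_2]$ intervals; setting both means equal produces the overlapping
regime.

What the generator does **not** emulate: MRI physics (bias fields, partial
volume, modality-specific contrast), motion or registration error between
timepoints, non-radial growth, perfusion deconvolution. Passing tests
therefore demonstrate the correctness of the algorithmic chain under known
geometry and perfusion structure — not robustness to acquisition
artefacts, which must be assessed on real data.

## Numerical choices and degenerate inputs

* Intensities are jointly min-max normalized per problem before
  optimization; the constants are stored on the path.
* Energies are evaluated with cached intensity gradients; the adjoint of
  the central-difference gradient is the matching negative divergence up
  to boundary rows, and backtracking guarantees monotone energy decrease
  regardless.
* A direction with no voxels yields an empty mask and an `NA` threshold; a
  direction with < 3 rMTT bins yields no fit, recorded in the phase notes.
* Uniform speeds (sd = 0) empty the highly-dynamic mask because the
  inequality is strict.
* Fits that fail to converge return the moment-based initial estimate
  flagged `converged = FALSE` with a warning.
* Non-binary masks are rejected before any computation.
* `generateCase()` restores the caller's RNG state; all randomness derives
  from the config seed, making cases byte-identical across runs.

## Problem sizes used in the shipped checks

The test-suite and the reproduction script use 2D problems: 24–32 voxel
grids for operator-level checks, 48×48 cases for pipeline plumbing, and
twenty 64×64 cases at 10 timesteps (12 with distinct generating means, 8
with identical ones) for the headline peak-recovery property, with the
optimizer capped at 200 iterations and `tol` $10^{-5}$. These sizes give
sub-voxel registration accuracy on the fixtures while a full run stays in
the minutes range on one CPU; the operators are dimension-generic, so 3D
volumes run unchanged, only slower.

## Known limitations

* The optimizer is first-order; very small `sigma` on large grids
  converges slowly. Geodesic shooting / adjoint formulations are out of
  scope.
* Inter-timepoint rigid alignment, skull stripping and DICOM conversion
  are assumed done upstream.
* The second phase registers to a pseudo-image rendered from the final
  lesion mask when no final image is available; with a true final image
  the photometric path absorbs the modality change instead.
* Cohort-level clinical correlations are deliberately not computed; the
  per-case metrics are exported so users can model them externally.
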