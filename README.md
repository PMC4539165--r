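# strokemorph

Phase-based metamorphosis analysis of ischemic stroke lesions: an R package
for quantifying *where* and *how fast* a diffusion-weighted (DWI) stroke
lesion expands or contracts over time, and which perfusion values those
dynamic areas experience.

It is aimed at neuroimaging researchers studying lesion evolution on
longitudinal MRI: acute DWI (hours after stroke), subacute DWI (~days), and
a final T2-weighted scan (≥ 1 month), with a mean-transit-time (MTT)
perfusion map per phase.

## The model

Between two timepoints, the lesion image is registered with a
**metamorphosis** model — a large-deformation diffeomorphic (LDDMM-type)
registration that jointly estimates a *geometric* path (a time-dependent
velocity field `v_t` whose flow deforms the image) and a *photometric* path
(pointwise intensity change, so the lesion can also appear or disappear).
The discrete path of intensity frames `I_0 … I_T` and velocities `v_t`
minimizes

```
U(I, v) = Σ_t |v_t|²_V Δt  +  (1/σ²) Σ_t ‖ (I_{t+1} − I_t)/Δt + ∇I_t · v_t ‖²_L2 Δt
```

where `|·|_V` is a smoothness norm realized by a Gaussian kernel and the
second term is the residual of the advection relation — the intensity
change not explained by transport. `σ` trades deformation smoothness
against fidelity; the endpoints are pinned to the observed images, so the
path fits every observation exactly. Optimization is alternating
backtracking gradient descent on momenta and interior intensity frames,
with steps that would fold the grid (Jacobian determinant ≤ 0) rejected.

From a converged path the package derives, per phase
(acute→subacute, subacute→final):

* a **signed total deformation map** over the lesion: time-integrated
  squared speed `Σ_t ‖v_t(x)‖² Δt`, signed + (expansion) or − (contraction)
  by the velocity's projection on the lesion's outward normal;
* **highly dynamic regions**: contracting voxels with speed above the
  contraction mean − sd, expanding voxels with speed above the expansion
  mean + sd, and their volumetric proportions of the lesion;
* an **rMTT map**: each lesion voxel's MTT divided by the mean MTT of the
  mirror-reflected (contralateral) lesion region — a unitless perfusion
  ratio;
* **Gaussian least-squares fits** of mean deformation versus rMTT, one per
  direction: the fitted peak `μ` is the perfusion level associated with the
  fastest deformation, and `[p1, p2] = [μ − s, μ + s]` its interval.

A synthetic-data module generates longitudinal cases (two-hemisphere
phantom, growing/shrinking lesion components, MTT maps with configured
rMTT–deformation structure) with known ground truth, so the entire pipeline
is testable without patient data.

## Worked example

```r
library(strokemorph)

case <- generateCase(caseConfig(seed = 7L))
case
#> SyntheticCase: grid 64x64, 2 lesion component(s), seed 7
#>   acute/subacute/final lesion voxels: 346 / 398 / 426
#>   subacute MTT available: TRUE

params <- metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = 10L,
                              maxIters = 200L, tol = 1e-5)
res <- runPhase(case, "acute-subacute", analysisConfig(params = params))
res
#> PhaseResult (acute-subacute)
#> DynamicRegions (rule: corrected)
#>   highly contracting: 128 voxels (36.99%), speed threshold 0.4966
#>   highly expanding:   24 voxels (6.94%), speed threshold 0.9003
#>   contraction fit: peak rMTT 1.499, interval [1.258, 1.741]
#>   expansion fit: peak rMTT 0.800, interval [0.606, 0.993]

confidenceInterval(res@fits$contraction)
#>       p1       p2
#> 1.257528 1.740656
```

This case was generated with rMTT centred at 1.5 around its contracting
component and 0.8 around its expanding component; the fitted peaks recover
both to three decimals, and the two `[p1, p2]` intervals are disjoint —
perfusion in the contracting areas is clearly distinct from perfusion in
the expanding areas for this case. The proportions say that ~37 % of the
lesion volume is contracting rapidly (the shrinking component) and ~7 %
expanding rapidly.

Real data enter through `readCaseDir()` (NIfTI volumes with fixed names
plus a `case.yaml` sidecar — see `?readCaseDir`), then `runCase()`,
`cohortSummary()` and `exportReport()`. A thin command-line wrapper with
`simulate` / `run` / `report` subcommands is installed at
`inst/scripts/strokemorph`.

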