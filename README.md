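# dpet4d

Temporally regularized 4D reconstruction of dynamic PET (dPET) data, built
around the **spline-residue** kinetic model, together with a desk-scale
dynamic scanner simulator and the bias/noise metric suite needed to compare
reconstruction algorithms.

## Who this is for

Researchers in PET image reconstruction and kinetic modelling who want a
self-contained, reproducible environment for studying how the choice of
temporal model affects 4D reconstruction: no scanner data or Monte-Carlo
photon transport is required — the package simulates dynamic sinograms of
thoracic-like digital phantoms with known ground truth.

## The method

Frame-by-frame reconstruction of dPET data leaves early, short frames very
noisy.  Nested-MAP 4D reconstruction alternates, for 30 iterations by
default:

1. one maximum *a posteriori* (MAP) image update per frame — an
   optimization-transfer step combining the EM surrogate of the Poisson
   likelihood `⟨y⟩ = Px + ε` with a separable surrogate of the
   edge-preserving Lange prior `ψ(ξ) = δ(|ξ|/δ − ln(1+|ξ|/δ))`;
2. a per-voxel fit of a temporal model to the updated TAC by penalized
   weighted least squares, `θ = (BᵀWB + γ′Ω)⁻¹ BᵀW x̂` with weights
   `w = 1/x`, the temporal weight `γ′` selected per voxel by generalized
   cross-validation over `{0.001, …, 0.01}`;
3. re-seeding the next MAP update with the model-predicted TACs.

Temporal model families: **spline-residue** (AIF ⊗ cubic B-splines of the
residue function, plus a blood term — constrained early, flexible late),
**spectral** (AIF ⊗ exponentials over 100 log-spaced decay constants),
**adaptive-knot cubic B-splines** (11 free knots per voxel placed along
equal segments of `∫|f''''|^{1/4}`), and the irreversible two-tissue
compartment model **2C3K**, whose macro-parameter is the trapping flux
`kflux = K1·k3/(k2+k3)`.

The simulator produces Poisson realizations of strip-integral sinograms
(~3.5 million counts per realization) for a thoracic slice with blood,
lung, bone and a tumour with normoxic rim and hypoxic core, acquired with
a dynamic FMISO protocol (frames from 5 s to 600 s, late frames at 2 h and
4 h, injection 30 s into scanning).  A "simplified" phantom uses 2C3K
kinetics everywhere; a "realistic-like" phantom uses kinetics the 2C3K
model cannot fit, separating algorithms by robustness to model
misspecification.

## Worked example

```r
library(dpet4d)

ph    <- makeReferencePhantom("simplified", n = 32)
sched <- defaultFrameSchedule()
geom  <- scannerGeometry(nAngles = 48, nBins = 47, n = 32)
sim   <- simulateScan(ph, sched, geom)        # calibrated to 3.5e6 counts
sino  <- samplePoisson(sim, seed = 5)

cfg <- reconConfig(nIter = 10, calibration = sim$calibration)
res <- nestedMAPReconstruct(sino, sim$P, "spline_residue", cfg,
                            aif = ph@aif, truth = sim$truth)
res
#> ReconResult (nested, spline_residue): 10 iterations, final objective 1.17217e+07

round(res@tmse)
#>  [1] 27893182 19170629 15857166 14048635 12746078 11665598 10730558
#>  [8]  9922691  9231179  8644711
```

The objective is the Poisson data log-likelihood of the model-predicted
images (rising as the fit improves); `tmse` is the truth-normalized,
time-weighted total squared error, which falls from 27.9M to 8.6M over ten
iterations — compared with 9.7M for the conventional (non-4D) MAP
reconstruction of the same sinogram, the temporal model is already paying
for itself.  Parametric maps then come from `parametricMap(res@images,
ph@aif, phantomSubRegion(ph))`, and `runExperiment(experimentSpec(...))`
drives the full conventional-vs-nested comparison over noise realizations.

A thin command-line driver covering simulate/reconstruct/experiment/
fixtures lives at `inst/scripts/dpet4d.R`.

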