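# resumeqmri

Quantitative MRI relaxometry from a susceptibility-weighted-imaging-compatible
protocol: one single-echo spoiled gradient-echo (GRE) acquisition plus one
multi-echo spoiled GRE at **doubled repetition time**, reconstructed
analytically into voxelwise **R1**, **R2\*** and **proton-density (PD)**
maps. The package is aimed at quantitative-MRI methods developers and
neuroimaging pipelines that want relaxometry from a standard clinical SWI
scan at the cost of ~50% extra scan time, without iterative fitting.

## The model

The steady-state complex signal of an ideally spoiled GRE is

    S = |K| M0 · sinθ · (1 − E1) / (1 − E1 cosθ) · exp(−TE (R2* + iγΔB) + iφ0),
    E1 = exp(−TR · R1)

With echoes `s_i` of the multi-echo sequence, `log s_i = k0 − TE_i · R2*`
is fitted voxelwise by weighted least squares with weights
`w_i = 1/(BW_i s_i²)`, giving R2\* and the TE = 0 intercept. Both
acquisitions are then extrapolated to TE = 0
(`S1 = s0 exp(TE0 R2*)`, `S2 = exp(k0)`), and the ratio `q = S1/S2`
obeys a quadratic in `E = exp(−TR0 R1)`:

    C E² − R E − (q − k) = 0,
    k = sinθ1/sinθ2,  R = q (1 − cosθ1),  C = q cosθ1 − k cosθ2

The physical branch is the "plus" root exactly when
`cosθ1 ≥ [1 + cosθ2 E(2+E)] / [1 + E(2 + cosθ2 E)]`; for `E > e⁻¹`
(TR0 < T1) the sufficient condition `θ1 < 0.47 θ2` guarantees it for every
θ2 in (0, π). Finally `R1 = −log(E)/TR0` and
`PD = S2 (1 − E² cosθ2) / (sinθ2 (1 − E²))`.

Around this core the package provides:

* a forward-model **digital phantom generator** (`simulate_protocol()`),
  so every stage is testable without scanner data;
* a **multispectral non-local-means denoiser** (`mnlm_denoise()`) with
  per-channel spatially varying noise maps, channel quality weighting and
  an adaptive search ball (compiled core + pure-R reference oracle);
* the **delta-method noise model** of the R1 estimate (`r1_variance()`),
  optimal flip-angle search (`optimal_flip_angles()`) and the R1-map SNR
  ratio (`r1_snr_ratio()`);
* **reproducibility/accuracy assessment**: the 2³ Cartesian ensemble of
  protocol realizations (`build_ensemble()`), voxelwise μ/σ maps with
  normalized-median summaries (`repro_stats()`), difference-magnitude
  accuracy maps (`accuracy_map()`) and ROI tables (`roi_stats()`);
* minimal **NIfTI-1 I/O**, JSON protocol sidecars, an end-to-end pipeline
  (`fit_resume()` in memory, `run_resume()` on disk) and a CLI
  (`inst/cli/resume`) with verbs `simulate`, `fit`, `denoise`, `assess`,
  `optimize-fa`.

## Worked example

```r
library(resumeqmri)

# three-compartment brain-like phantom at the reference protocol
# (TR 14/28 ms, TE 7.63/22.14 ms, flip 2/20 degrees, BW 190 Hz/px)
spec <- default_phantom_spec(32)
sim  <- simulate_protocol(spec)
maps <- fit_resume(sim$single, sim$dual)
print(maps)
#> Quantitative map bundle: grid 32x32x32, 9680/32768 voxels valid
#>   failure codes: 1:23088

roi_stats(maps$r1, sim$labels)
#>   label    n  mean sd
#> 1     1 8516 1.080  0
#> 2     2  968 0.624  0
#> 3     3  196 0.250  0
```

The three regions recover their ground-truth R1 (1.08, 0.624 and
0.25 1/s for the white-matter-, grey-matter- and CSF-like compartments)
exactly in the noiseless limit; code 1 marks background voxels without
signal. With noise, `fit_resume(..., denoise = TRUE)` runs the
multispectral filter on the three magnitudes (plus an optional
susceptibility channel) before mapping, and

```r
fa <- optimal_flip_angles(0.014)   # R1 * TR0 for T1 = 1 s at TR0 = 14 ms
print(fa)
#> Optimal flip angles: theta1 = 4.333 deg, theta2 = 35.302 deg
#> (ratio 0.123), sigma_R1 = 0.4052 1/s
```

reports the flip-angle pair minimizing the delta-method R1 variance per
unit image noise.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the analytic branch-selection bound from scratch: it solves the
branch-condition equality for θ1 on a dense θ2 grid over (0, π) at
`E = e⁻¹` and reports the minimum of θ1/θ2 (target `t1`).
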