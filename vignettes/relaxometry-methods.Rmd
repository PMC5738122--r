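---
title: "Analytic dual-GRE relaxometry: model, noise behaviour and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic dual-GRE relaxometry: model, noise behaviour and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resumeqmri)
```

## The reconstruction problem

A clinical susceptibility-weighted scan is a 3D spoiled gradient-echo (GRE)
acquisition with a long echo time. Sampling one extra early echo turns it
into a multi-echo GRE, which already supports R2\* mapping; adding a second
spoiled GRE at *half* the repetition time and a lower flip angle makes the
pair sufficient for R1 and proton-density (PD) mapping as well — a complete
relaxometry protocol for about 50% extra scan time. This package
implements the analytic reconstruction for that two-sequence scheme:

* single-echo GRE: repetition time $T_{R,0}$, echo time $T_{E,0}$, flip
  angle $\theta_1$ (reference protocol: 14 ms / 7.63 ms / 2°);
* multi-echo GRE: repetition time $2T_{R,0}$, echo times $\{T_{E,i}\}$,
  flip angle $\theta_2$ (28 ms / {7.63, 22.14} ms / 20°, 190 Hz/px).

All computation is in SI units (seconds, radians); configuration files
accept milliseconds and degrees and are converted at parse time, removing a
whole class of unit bugs.

## Signal model and the closed-form solution

The spoiled-GRE steady state is
$$S = |K| M_0 \sin\theta \,\frac{1-E_1}{1-E_1\cos\theta}\,
      e^{-T_E (R_2^* + i\gamma\Delta B) + i\phi_0},
      \qquad E_1 = e^{-T_R R_1}.$$
Coil sensitivity magnitude $|K|$ is inseparable from $M_0$ in magnitude
data, so the package's "PD" is $|K| M_0$ throughout (optionally divided by
a supplied receive-field map, or normalized to a CSF region).

**R2\*** comes from the voxelwise weighted least-squares fit of
$\log s_i = k_0 - T_{E,i} R_2^*$ with weights $w_i = 1/(\mathrm{BW}_i
s_i^2)$ — the inverse variance of $\log s_i$ when the image-domain noise
power scales with the receiver bandwidth. For two equal-bandwidth echoes
this reduces exactly to $R_2^* = \log(s_1/s_2)/(T_{E,2}-T_{E,1})$, an
identity the test suite asserts on random inputs. Voxels with fewer than
two positive echoes are masked, never raised as errors.

**R1**: extrapolating both sequences to $T_E = 0$
($S_1 = s_0 e^{T_{E,0} R_2^*}$, $S_2 = e^{k_0}$) and forming
$q = S_1/S_2$ eliminates $|K| M_0$; with the doubled repetition time the
dual-sequence recovery factor is $E_{1,0}^2$, and $q$ satisfies the
quadratic $C E^2 - R E - (q - k) = 0$ with $k = \sin\theta_1/\sin\theta_2$,
$R = q(1-\cos\theta_1)$, $C = q\cos\theta_1 - k\cos\theta_2$.

### Branch selection

Both quadratic roots satisfy the signal relation algebraically, so
"substitute back and check" cannot disambiguate them; the discriminating
fact is a closed-form condition: the plus root is the physical one iff
$$\cos\theta_1 \ge \frac{1 + \cos\theta_2\, E(2+E)}{1 + E(2 +
\cos\theta_2 E)}.$$
The condition involves the unknown $E$, but for $E > e^{-1}$ (i.e.
$T_{R,0} < T_1$, true for every tissue at the reference protocol) the
sufficient rule $\theta_1 < 0.47\,\theta_2$ selects the plus branch for
any $\theta_2 \in (0, \pi)$. The implementation therefore:

1. takes the plus root unconditionally when $\theta_1 < 0.47\,\theta_2$;
2. otherwise evaluates the condition *at each candidate root*: the plus
   root is self-consistent if the condition holds at it, the minus root if
   the condition fails at it; a unique self-consistent root in $(0,1)$ is
   kept, anything else is masked as ambiguous (code 5). A warning reports
   that the protocol is in the ambiguous regime.

Numerically, the stable conjugate form is used for the smaller root
($R \ge 0$ always, so $R + \sqrt{R^2 + 4C(q-k)}$ never cancels), and
$|C| < 10^{-12}|R|$ falls back to the linear root $E = (k-q)/R$. The
boundary case $q = k$ (fully relaxed, $E = 0$) is masked as non-physical.
Voxels failing any stage carry a per-stage code in the validity mask
(1 R2\* fit, 2 extrapolation, 3 discriminant, 4 root range, 5 ambiguity,
6 PD denominator) and `NA` in the maps — downstream code never sees silent
garbage.

The minimum of $\theta_1/\theta_2$ along the equality locus of the branch
condition at $E = e^{-1}$, computed by `branch_boundary_ratio()` over a
dense $\theta_2$ grid, is ≈ 0.4743 — strictly above 0.47, which is what
`scripts/acceptance.R` re-derives (target `t1`). The infimum is approached
as $\theta_2 \to \pi$, so the grid must run close to that endpoint.

### Repetition times other than 2:1

The quadratic exists only because the dual-sequence recovery factor is
exactly $E^2$. For other TR ratios the package warns and, in an explicit
`general_tr` mode, solves the generalized relation per voxel by bracketed
root finding on $(0,1)$ — slower, and intentionally opt-in, because the
closed form is the point of the method.

## Noise model, optimal flip angles

With equal bandwidth on both acquisitions, $S_1$ and $S_2$ share one noise
power $\sigma_S$, and the delta method gives
$$\sigma^2_{R_1} = \left[\left(\frac{\partial E^+}{\partial S_1}\right)^2
 + \left(\frac{\partial E^+}{\partial S_2}\right)^2\right]
 \left(\frac{\sigma_S}{T_{R,0} E}\right)^2.$$
The derivatives are implemented analytically by differentiating the
closed-form root with respect to $q$ (a central-difference oracle guards
the algebra in the tests to $10^{-5}$ relative). Monte-Carlo simulation at
SNR 100 reproduces the predicted standard deviation within 1–2%.

Two implementation facts worth recording:

* The plus-branch variance expression is meaningless where the plus branch
  is not the physical root; the unconstrained minimizer actually lies in
  such a spurious basin (near 45°/60°). `r1_variance()` therefore errors
  outside the validity region, and `optimal_flip_angles()` restricts its
  deterministic two-stage search (1° coarse grid on $(0,\pi/2)^2$, then
  Nelder-Mead refinement at `reltol = 1e-14`) to admissible pairs. The
  optimum is interior, stable to the coarse-grid resolution (1° vs 0.5°
  agree within 0.05°), and its $\bar\theta_2$ grows monotonically with
  $R_1 T_{R,0}$.
* `predict_r1_sd()` extends the delta method through the whole chain —
  per-echo noise enters $S_1$ and $S_2$ jointly via the R2\* fit — with
  the full analytic Jacobian. On a uniform white-matter phantom at SNR 100
  the end-to-end prediction matches the observed scatter to < 1%.

`r1_snr_ratio()` normalizes the R1-map SNR to the input-image SNR in
average parenchyma ($T_{1,\mathrm{par}} = 1$ s). The input-image SNR is
taken on the $T_E = 0$ amplitude of the double-TR sequence (the higher-SNR
input); the noise level cancels, so the ratio depends only on the protocol
and the expected $T_1$.

## Multispectral non-local means

The denoiser treats the co-registered magnitudes (plus an optional
susceptibility map) as one multichannel image. For channel $m$,
$$Y_m(x) = \frac{\sum_{y \in B_r[x]} W_m(x,y)\, X_m(y)}
                 {\sum_{y \in B_r[x]} W_m(x,y)},\qquad
  W_m(x,y) = \exp\!\left[-\frac{d^2(x,y)}{\varsigma^2}\,
  \frac{Q_m}{\sum_l Q_l}\right],$$
where $d^2$ is the Gaussian-windowed patch distance summed over channels
and normalized voxelwise by $\sigma_m^2(x) + \sigma_m^2(y)$, and
$Q_m = \sum_\Omega X_m^2 / \sum_\Omega \sigma_m^2$ is the channel quality
factor (low-SNR channels are smoothed harder and weigh less in the shared
distance). Defaults follow the field guidance tied to the voxel volume
$\Delta V$: $\kappa = 100\,\Delta V$, $\rho = 5\,\Delta V^{1/3}$,
$\varsigma = 1$.

Discretization choices (all shared bit-for-bit between the compiled path
and the pure-R reference loop):

* the Gaussian window is truncated per axis at $2\rho$ and built as the
  product of per-axis-normalized 1D kernels, so it is exactly separable;
  anisotropic voxel sizes enter through physical distances;
* the search ball grows in shells of equal voxel-center distance until the
  accumulated weight times $\Delta V$ reaches $\kappa$ (per channel), with
  a cap at three uniform-weight ball radii; capped voxels are flagged;
* the self-weight $W_m(x,x) = 1$ is always included, making every output a
  convex combination of in-ball inputs (asserted as an invariant);
* windows beyond the volume use reflective padding; $\kappa$'s
  normalization (weight sum × voxel volume) is our reading of the
  volume-units convention, and $\sigma_m^2$ in $Q_m$ is integrated over
  the support as a channel constant — both conventions are ambiguous in
  the original formulation and are fixed here once;
* non-finite voxels are excluded as centers and neighbors and flagged;
  zero-noise inputs receive a tiny sigma floor, which makes the filter a
  near-exact identity on noiseless data (asserted to 1e-10 through the
  full pipeline).

The compiled core evaluates the patch distance offset-by-offset as a
separable convolution of the squared-difference image, with early
termination once every voxel has met its budget; it matches the
quadruple-loop R reference to ~1e-15 relative on oracle volumes. Measured
on one CPU of this container, a 64³ four-channel volume takes ~40 min at
the default parameters and ~13 min at $\rho = 2$ mm (achieving a 13x
within-region noise reduction with negligible bias). The dominant cost is
not the patch but the search cap: any voxel that cannot meet its weight
budget (14% here, near edges and boundaries) forces the shell loop to the
full cap of ~2700 offsets, each a volume-wide convolution. A one-minute
CPU reference for this filter is not realistic at these settings — the
original pipeline used a multi-GPU implementation for exactly this stage —
so that performance aspiration is recorded here as unmet on CPU hardware.
Runtimes in the test suite stay small by using 8³–24³ volumes and tighter
search caps.

When no noise map is supplied, a block-wise robust estimator substitutes
for a full noise-field estimation algorithm (out of scope): the residual
against a 3³ box mean, summarized per 5³ block by the
Gaussian-consistent MAD with a $\sqrt{26/27}$ correction for the variance
removed by the mean. It overestimates near strong edges; calibrated
noise maps should be supplied when available.

## The phantom generator: what it emulates, what it does not

`simulate_protocol()` produces exactly the two-sequence acquisition from
piecewise-constant tissue regions (axis-aligned boxes/ellipsoids painted
in order), smooth low-order-polynomial coil-sensitivity and transmit
fields normalized to unit mean, and additive Gaussian noise on the
magnitudes with optional spatially varying sigma, clipped at zero and
flagged. One master seed derives per-echo streams; output is
bit-reproducible.

Deliberate simplifications: Gaussian (not Rician) magnitude noise —
adequate at SNR ≫ 3, i.e. everywhere this protocol operates, and wrong in
air; no partial-volume effects, so ground truth is exact per voxel; no
k-space effects (GRAPPA, flow, slice profiles, magnetization transfer). A
green round-trip test therefore establishes the correctness of the
analytic inversion and its noise model, not robustness to acquisition
physics outside the signal equation.

Default tissue values are typical 3 T brain numbers (WM R1 = 1.08 1/s,
R2\* = 21.1 1/s, PD = 0.718; cortical GM 0.624 / 15.1 / 0.852; CSF-like
0.25 / 1.0 / 1.0, PD normalized to CSF). The miniature ellipsoid phantom
is structure-dense: at test sizes (16³–64³) almost every patch of the
default 21³ window straddles a region boundary, and the denoiser —
correctly — refuses to smooth. Denoising benchmarks therefore use either
large flat regions (64³ slabs) or a layered phantom with patch radii
proportionate to the structure scale (ρ = 1.5–2 mm); this is a property of
the scaled-down geometry, not of the filter.

## Reproducibility assessment

With each sequence acquired twice, the three magnitude inputs
($s_0, s_1, s_2$) can be drawn from either repetition: $2^3 = 8$ complete
reconstructions, ordered by binary counting (repetition A = 0, bit 0 =
$s_0$). `repro_stats()` reduces the ensemble to voxelwise mean and
standard-deviation maps and summarizes each map by the median σ within a
mask, normalized to the range of the mean map in percent. Choices the
original description leaves open, fixed here:

* sample standard deviation uses the n−1 convention (material at n = 8,
  recorded in the report);
* the range of the mean map is outlier-sensitive, so the headline number
  discards the extreme 0.1 percentiles; the unclipped variant is reported
  alongside; a degenerate (zero) range yields an undefined summary,
  reported as such rather than silently dropped.

One statistical fact matters when comparing ensemble spread with the
delta-method prediction: the 8 realizations reuse two draws of each of
three inputs, so for a (locally linear) estimator the voxelwise sample
variance has expectation exactly $4/7$ of the single-shot variance — the
three squared input-contrasts each enter as $\Sigma(v-\bar v)^2 =
2(\Delta)^2$ with $E[(\Delta)^2] = 2\sigma^2$, giving $E[s^2] =
\tfrac{4}{7}\sigma_{\mathrm{tot}}^2$ (confirmed by simulation). The
acceptance test for the ensemble machinery therefore compares the rms
$\sigma_j$ in white matter against $\sqrt{4/7}$ times the full-chain
prediction, at the 30% tolerance appropriate to an 8-member ensemble.
Accuracy maps are plain voxelwise $|{\rm map} - {\rm reference}|$ with the
same normalized-median summary (normalized to the reference range); ROI
tables report mean ± sd per label with optional CSF normalization of PD.
In-vivo reproducibility figures (medians of order 1–3%) depend on scanner
data and are not reproduced at desk scale; the package reproduces the
machinery and its statistical contracts instead.

## Field-inhomogeneity correction

Transmit (B1+) nonuniformity scales the true flip angles; given an
externally measured map, `fit_resume(b1 = ...)` uses
$\theta_{1,2}\,b_1(x)$ voxelwise in the root selection and PD inversion
(the receive profile cancels in $q$ and only biases the PD scale, divided
out by an optional receive map). Simulations with a 10% transmit dip show
exact recovery with the true map and a >1% R1 bias without it. The
iterative, information-theoretic self-calibration used in the original
work is out of scope; only the external-map hook is provided.

## Known limitations

* Gaussian magnitude-noise model (no Rician floor): background statistics
  are not faithful.
* The denoiser's default patch (2ρ ≈ 8 mm) assumes structure sparser than
  a miniature phantom; see above.
* `general_tr` mode trades the closed form for per-voxel root finding.
* QSM is consumed only as an optional denoising channel, never
  reconstructed.
* Phase images pass through untouched; $\phi_0$/$\Delta B$ estimation is
  out of scope.
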