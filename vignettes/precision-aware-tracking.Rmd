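---
title: "Pointwise localization precision and uncertainty-aware tracking"
author: "locprec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pointwise localization precision and uncertainty-aware tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locprec)
```

## The problem

Single-particle tracking and localization microscopy estimate the position
of individual fluorophores from noisy camera images. The *precision* of
each localization varies strongly along a trajectory — with photon count,
defocus, motion blur and background — yet most downstream analyses either
ignore it or assume a single theoretical value. This package implements an
integrated stack in which every localization carries its own uncertainty
estimate, and in which the downstream estimators (diffusion constants,
diffusive-state segmentation, trajectory smoothing) consume those
uncertainties explicitly.

## Image model

### EMCCD counts

A pixel that expects `E` photons produces an offset-subtracted count `c`
through electron multiplication and readout. We use the standard high-gain
approximation: the number of photons is Poisson(`E`), each photon's
amplified electron count is Exponential with mean `gain`, so the amplified
signal given `n >= 1` photons is Gamma(`n`, `gain`), and summing over `n`
gives a Bessel-type density plus a discrete atom `exp(-E)` at zero. Readout
noise convolves everything with a zero-mean Gaussian of s.d. `readout_sd`.
`log_pcount()` evaluates the log of this density; `sample_counts()` draws
from exactly the same generative chain, so likelihood and simulator cannot
drift apart (a Monte-Carlo histogram test enforces this).

Numerics: the convolution integral is evaluated by fixed-order (33)
Gauss–Legendre quadrature over the amplified-electron variable, restricted
to the +/- 9 s.d. support of the readout Gaussian. The EM density has a kink
at zero; integrating in this variable keeps the kink on an interval
endpoint, which is what lets the density normalize to 1 to better than
1e-6 (quadrature over the readout variable instead converges only
algebraically there). The scaled Bessel function `I_1(s) exp(-s)` uses the
classical Abramowitz–Stegun polynomial approximations (relative error
~5e-7, an order of magnitude faster than `besselI` and well inside every
tolerance used here); `besselI` remains the oracle in the test suite. The
variance of the cascade is `2 gain^2 E + readout_sd^2` per pixel — the
factor 2 is the EMCCD excess noise that also appears in the CRLB below.

### Spot shape

The expected photon map is a constant background `b` (photons/pixel) plus
`N` (photons/spot) times a pixel-integrated Gaussian profile, either
symmetric (width `sigma`) or asymmetric (principal widths `sigma1`,
`sigma2` and rotation `phi`, i.e. a bivariate Gaussian with covariance
`R(phi) diag(sigma1^2, sigma2^2) R(phi)^T`). Pixel integrals use a
tensor-product Gauss–Legendre rule of order 5 per axis, which agrees with
the closed-form erf product to better than 1e-6 relative for widths at and
above half a pixel; the symmetric fit path uses the separable form of the
same rule. Pixels are half-open squares, `(i, j)` covering
`[i a, (i+1) a) x [j a, (j+1) a)` with 0-based indices and pixel size `a`.

## Localization and pointwise precision

`fit_spot()` minimizes the negative log-posterior in internal coordinates
(position in pixels; `ln N`, `ln b`; width as `ln sigma` for MLE and
`ln delta_sigma` for MAP) by BFGS from a seed position. The MAP priors
encode two cheap pieces of physics:

* the spot cannot be narrower than a diffraction-limited spot,
  `sigma0 = 0.21 lambda / NA` (95.85 nm at 639 nm and NA 1.4), enforced
  structurally by the reparameterization
  `sigma = sigma0 (1 + delta_sigma)`, with an exponential prior of mean 1
  on the excess width `delta_sigma` (mean 1/2 per principal width for the
  asymmetric model);
* the background has a known order of magnitude: a weak normal prior with
  s.d. `log(30)` on `ln b`, centred on a user-supplied value or on the ROI
  border estimate.

The prior is a density in `(delta_sigma, ln b)`; the `ln delta_sigma`
Jacobian is included in the internal objective, so the optimum maximizes
the posterior density in the stated variables. Position and amplitude keep
flat priors. With all priors flat the MAP objective is exactly the MLE
objective (tested to 1e-12).

Pointwise precision comes from the Laplace approximation: the Hessian of
the objective at the optimum (central differences, step 1e-4 in internal
coordinates), inverted to the posterior covariance; the reported per-axis
precision is the marginal s.d. of the position from the full inverse, not a
1-D curvature. Fits with a non-positive-definite Hessian are flagged and
report no precision. The analytic CRLB benchmark
(`crlb_precision()`) uses the Rieger–Stallinga approximation with
`sigma_a^2 = sigma^2 + a^2/12`, `tau = 2 pi sigma_a^2 b / (N a^2)` and an
overall factor 2 on the variance for EMCCD excess noise.

Post-fit filtering retains fits that converged, lie within 4 pixels
(Euclidean) of their reference position, have estimated uncertainties below
16 pixels, and widths below 9 pixels (the ROI size).

One intrinsic subtlety, surfaced by the "noise-free image" self-test: if
every count is set to its conditional mean, the fitted background exceeds
the generating value by roughly half a photon, because the skewed EM
cascade density has its per-pixel maximum-likelihood intensity above the
mean. Position, amplitude and width are unaffected at high photon counts.

## Motion blur and the shutter

A camera pixel integrates over the exposure, so the observed position is a
shutter-weighted average of the true path. For a normalized shutter
`f(t)` on one frame interval with cumulative `S(t)`, three constants
summarize everything the tracking models need:

* `R = (1/dt) * integral S (1 - S) dt` — the blur coefficient, in
  `[0, 1/4]`; 1/6 for continuous illumination, 0 for an instantaneous
  exposure, 1/4 for half-weight impulses at both frame ends;
* `tau` — the shutter's first moment (fraction of the frame);
* `beta = tau (1 - tau) - R` — the residual observation variance
  coefficient.

`blur_constants()` computes all three exactly for piecewise-constant
densities and for atom trains (so the canonical anchors are exact, not
quadrature approximations). The measured steps of a freely diffusing
particle then have `Var(dx) = 2 D dt (1 - 2R) + 2 eps^2` and
`Cov(dx_k, dx_{k+1}) = 2 D dt R - eps^2`, uncorrelated at larger lags.

A scaling argument classifies exposures: the in-plane s.d. of the diffusion
path around its exposure average is `sqrt(D t_E / 3)` per axis (the 1/3 is
the time-averaged variance of a Brownian bridge-like deviation, verified by
a Monte-Carlo oracle in the tests); `blur_ratio()` divides this by
`sigma0`, and ratios below 0.5 — below about 6–7 ms at `D = 1 um^2/s` with
the default optics — are weak blur.

## Diffusion estimators

For a single state, `d_cov()` combines both step moments so blur and
localization error cancel: `D = <dx^2>/(2 dt) + <dx_k dx_{k+1}>/dt`.
When the mean error variance is known — e.g. the average of the
Laplace-estimated variances along the trajectory — `d_cov_eps()` uses the
first moment alone, `D = (<dx^2> - 2 mean_eps2) / (2 dt (1 - 2R))`, which
is dramatically tighter on short trajectories. Negative estimates are
retained (flagged, not clamped) so ensemble averages stay unbiased.
`mle_diffusion()` maximizes the exact Gaussian likelihood of the
state-space form below (the single-state case of the HMM) and uses the
pointwise, rather than average, error variances; its advantage over
`d_cov_eps()` appears only when errors are strongly heterogeneous within a
trajectory, consistent with the moment estimators' robustness on
homogeneous data.

`correct_D()` implements the step-variance matching corrections for
simplified models: `D* = D_fit / (1 - 2R)` for a Kalman-type fit (errors
modelled, blur not) and `D* = (D_fit - mean_eps2/dt) / (1 - 2R)` for a
displacement-only fit.

## The multi-state diffusive HMM

### Model

Per axis (axes share the state sequence), with `T` frames:

* a Markov chain `s_t` with transition matrix `A` per frame and initial
  distribution `pi`;
* a Brownian path sampled at frame boundaries,
  `y_{t+1} = y_t + N(0, 2 D_{s_t} dt)`;
* observations `x_t = (1 - tau) y_t + tau y_{t+1} + eta_t` with
  `Var(eta_t) = eps_t^2 + 2 D_{s_t} dt beta`.

The two-point `(tau, beta)` embedding reproduces the exposure-averaged
step covariances exactly for any valid shutter — conditionally on the
interval endpoints, the shutter average of the intra-frame bridge is
`(1 - tau) y_t + tau y_{t+1}` with residual variance `2 D dt beta` — so no
sub-frame discretization of the latent path is needed; the tests verify
the embedding by simulating sub-stepped paths and matching all three
moments. The state of interval `t -> t+1` governs frame `t`'s observation
variance, since that is when the frame's photons are collected.

### Inference

`vem_fit()` maximizes an evidence lower bound with the factorized posterior
`q(s) q(y)`: forward–backward for `q(s)`; for `q(y)` the posterior is a
Gaussian chain with tridiagonal precision, handled by an LDL^T
factorization with exact recursions for means, marginal variances and
lag-one covariances (cost linear in `T`). The first path point carries a
flat prior. `pi` and `A` have closed-form updates; `D_k` is maximized
exactly by 1-D search on `ln D` (closed form when `beta = 0`). The ELBO is
assembled from its four exact pieces and asserted non-decreasing at every
iteration; for `K = 1` the factorization is exact and the converged ELBO
equals the marginal log-likelihood computed independently by a dense
Gaussian solve (tested to 1e-6).

Two optimization details matter in practice. First, initialization: the
vEM objective has well-separated local optima in `D`, and naive starts
systematically land in basins whose slow-state estimate is inflated by
soft state assignments. The default first start therefore comes from a
cheap displacement-HMM segmentation whose diffusion constants are
blur/noise-corrected; log-spaced and jittered starts follow. Second, basin
hopping: after the restarts, the fit is re-run from the incumbent with each
state's `D` shrunk (and all grown), keeping the best ELBO. Both devices
select purely by ELBO; on two-state benchmark data they move the median
slow-state estimate from ~30% high to within a few percent of truth.

States are sorted by ascending `D` after fitting; misclassification against
a known truth is computed after the same relabeling. `limit_fit()` exposes
the Kalman-type limit (`tau = beta = R = 0`, errors kept) and the
vbSPT-type limit (additionally `eps = 0`), the latter as an exact HMM on
raw displacements. When the full model is requested on data that are
exactly error-free and blur-free it reduces to the displacement HMM, which
is the exact marginal in that degenerate case.

### Refinement

`refine_positions()` reports the posterior mean and s.d. of the quantity
each measurement estimates: the shutter-averaged position of the frame.
That average decomposes into the two-point combination
`(1 - tau) y_t + tau y_{t+1}` plus an independent intra-frame bridge
deviation of variance `sigma_b^2 = 2 D dt beta` — and the measurement
itself is the only source of information about the bridge term. The
refined estimate therefore blends the path posterior with the data,
`(1 - w) [(1 - tau) m_t + tau m_{t+1}] + w x_t` with
`w = sigma_b^2 / (sigma_b^2 + eps_t^2)`, and its variance combines the
deflated two-point posterior variance with the bridge-measurement
conditional variance. All limits come out right: a static emitter with
equal errors gives `eps / sqrt(n)` exactly; `eps -> 0` returns the
measured positions for any shutter; a blur-free shutter gives the pure
path posterior. Per-frame refined s.d. can exceed the raw precision; the
improvement is an ensemble statement, largest for slow states with poor
localizations. (An earlier design that reported only the two-point
combination is measurably worse when localization errors are small
compared to the blur scale — it discards the bridge information the
measurement carries.)

## The synthetic-data generator

`sim_scenario()`/`simulate_path()`/`render_movie()` emulate a
single-molecule movie: Brownian motion (optionally multi-state, optionally
scripted) in a cylinder of length 20 um and diameter 0.8 um — a long
E. coli-like cell, chosen so longitudinal confinement is negligible — with
specular reflection at the wall and caps; sub-frame integration (20
substeps per frame by default) for motion blur; a Gaussian-beam defocus law
`sigma(z) = sigma0 sqrt(1 + (z/z_R)^2)` with `z_R = 400 nm`; a uniform
background, optionally decaying exponentially in time; and EMCCD counts
drawn by `sample_counts()`. Defaults follow the canonical bench conditions:
`D = 1 um^2/s`, 80 nm pixels, EM gain 50, readout s.d. 10, 639 nm/NA 1.4
optics. Expected photons are deposited per substep through the
pixel-integration rule, and Poisson noise enters at the camera stage —
statistically identical to drawing and binning individual photons.

`binding_scenario()` scripts the two-state benchmark: alternation between
free diffusion (1 um^2/s) and slow "bound" diffusion (0.1 um^2/s) at
200 Hz under continuous illumination with 300 photons/spot and a background
decaying from 0.95 to 0.75 photons/pixel with a 0.75 s time constant; four
binding events of different durations, two at z ~ 400 nm (about one cell
radius, as for membrane binding). The event positions at 13–23%, 33–38%,
53–63% and 73–78% of the trace and the z levels (400, 0, 400, 0 nm) are
this package's own layout choices.

`synth_hmm_tracks()` generates trajectories at the track level (no images):
sub-stepped paths, shutter-weighted averages and heteroscedastic Gaussian
errors. The shutter is discretized onto substep midpoints and the
*discretized* shutter is returned with the tracks, so moment tests compare
against its exact blur constants rather than an approximation.
`binding_tracks()` derives the per-frame error s.d. for the binding
scenario from the imaging model — the CRLB at the defocus-broadened,
blur-inflated width, the scenario's photon count and the decaying
background — with lognormal scatter (s.d. 0.15 in the log) for intensity
fluctuations. This track-level shortcut is what makes hundreds of
replicate fits affordable in the benchmarks.

### What the generator does and does not emulate

It captures the noise sources that drive pointwise precision: shot noise,
EM excess noise, readout, background, motion blur and defocus broadening.
It does not implement a vectorial high-NA PSF — defocus is a symmetric
Gaussian broadening, which is milder than the ring-structured defocus of a
real NA 1.4 objective — nor photobleaching, blinking, drift, or spot
detection (seeds are given). Consequences worth stating: passing
calibration tests show the estimator chain is self-consistent under this
generative model, not that a real microscope's defocused spots are this
benign; in particular, defocused localization errors here grow only ~1.6x
at z = 400 nm, so model-comparison gaps that feed on large error
heterogeneity (e.g. displacement-only HMMs failing on defocused events)
are much smaller here than with a vectorial PSF.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `gain` | `camera_model` | 50 | EM gain, e-/photon |
| `readout_sd` | `camera_model` | 10 counts | readout noise |
| `pixel_size` | `camera_model` | 80 nm | back-projected pixel |
| `sigma0` | `prior_config` | 0.21 lambda/NA | diffraction limit |
| `excess_width_mean` | `prior_config` | 1 (1/2 asym.) | prior mean of `delta_sigma` |
| `log_background_sd` | `prior_config` | `log(30)` | background prior width |
| `z_R` | `sim_scenario` | 400 nm | defocus depth scale |
| `substeps` | `sim_scenario` | 20 | blur discretization |
| `restarts`, `hops` | `vem_fit` | 5, 1 | optimization effort |
| `tol` | `vem_fit` | 1e-8 | relative ELBO convergence |

## Problem sizes used by the test suite

The shipped tests run the calibration on 2000 rendered spots; diffusion
ensembles of 1000 ten-step trajectories per noise level; HMM recovery on
100 replicates of 1000-frame two-state trajectories; and the binding
benchmark on 200 replicates of a 500-frame scenario with single-start
(plus basin-hopping) fits. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping the suite's
runtime moderate on a single core.

## Known limitations

* The Laplace precision is a curvature statement; for very dim or strongly
  defocused spots the posterior is non-Gaussian and the estimate degrades
  (the filtering step removes the worst cases).
* The vEM's factorized posterior biases parameter estimates where state
  uncertainty is high; the initialization and basin-hopping defaults
  mitigate but cannot remove this, and single-trajectory slow-state
  estimates remain noisy at low SNR.
* Trajectories must be gap-free and uniformly sampled; there is no model
  selection over the number of states, and no 3D or engineered-PSF
  localization.
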