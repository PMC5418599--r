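# locprec

Pointwise localization precision and uncertainty-aware tracking for
single-molecule microscopy.

Super-resolution localization microscopy and single-particle tracking (SPT)
estimate fluorophore positions from noisy EMCCD images. The statistical
quality of each localization varies enormously along a trajectory — with
photon count, defocus, motion blur and background — and analyses that
assume a single "typical" precision mis-estimate diffusion constants, miss
binding events, and over-trust bad points. `locprec` implements a stack in
which every localization carries its own uncertainty, and the downstream
estimators use it:

* **EMCCD likelihood** — high-gain electron-multiplication cascade
  (Poisson × Exponential gain, a Bessel-type density with an atom at zero)
  convolved with Gaussian readout noise; the same model drives the
  simulator's `sample_counts()`.
* **MAP localization** (`fit_spot`) — pixel-integrated Gaussian spot models
  (symmetric or asymmetric) fitted by quasi-Newton minimization, with
  physics-based priors: the spot width is reparameterized as
  `sigma = sigma0 (1 + delta_sigma)` with `sigma0 = 0.21 lambda / NA`, an
  exponential prior on the excess width `delta_sigma`, and a weak
  log-normal prior on the background.
* **Pointwise precision** — the Laplace approximation (inverse Hessian at
  the optimum, marginal position s.d.) per spot, and the analytic CRLB
  `var = 2 (sigma_a^2/N) (1 + 4 tau + sqrt(2 tau/(1+4 tau)))` with
  `sigma_a^2 = sigma^2 + a^2/12`, `tau = 2 pi sigma_a^2 b/(N a^2)` as a
  benchmark.
* **Blur-aware diffusion estimators** — covariance-based estimators with
  and without precision information, built on the step covariances
  `Var(dx) = 2 D dt (1-2R) + 2 eps^2`,
  `Cov(dx_k, dx_{k+1}) = 2 D dt R - eps^2`, where the shutter-dependent
  blur coefficient `R` (1/6 for continuous illumination) comes from
  `blur_constants()`; plus an exact-likelihood estimator using pointwise
  errors and heuristic corrections for simplified models.
* **Multi-state diffusive HMM** (`vem_fit`) — hidden diffusive states with
  motion blur and per-frame localization errors, inferred by variational
  EM over a factorized posterior (forward–backward × Gaussian chain), with
  Kalman-type and vbSPT-type limits (`limit_fit`), state classification
  and posterior **position refinement** (`refine_positions`) that can beat
  single-image precision by borrowing strength from neighbouring frames.
* **Synthetic movie generator** — multi-state Brownian motion in an
  E. coli-like cylinder, motion blur by sub-frame integration,
  Gaussian-beam defocus, decaying background, EMCCD noise, with full
  ground truth; every stage of the package is testable without external
  data.

## Worked example

Simulate a movie of a diffusing emitter, localize every frame with MAP,
and compare estimated against true errors:

```r
library(locprec)
set.seed(11)

scn <- sim_scenario(D = 1, frame_interval = 0.001, photons = 600,
                    background = 1, z_script = 0)   # in focus, weak blur
truth <- simulate_path(scn, n_frames = 300)
mov <- render_movie(scn, truth)

pr <- prior_config(sigma0 = sigma0(639, 1.4))       # 95.85 nm
fits <- lapply(seq_len(300), function(t) {
  ex <- extract_roi(mov$stack[, , t], c(mov$seeds$x_px[t], mov$seeds$y_px[t]))
  fit_spot(ex$roi, scn$cam, mode = "map", priors = pr,
           init = ex$seed_in_roi, roi_origin = ex$origin)
})
fits[[1]]
#> Spot fit (MAP, symmetric model)
#> Gaussian spot (symmetric): mu = (590.9, 577.7) nm, N = 636.8, b = 0.836
#>   sigma = 101.1 nm
#>   Laplace precision: sd_x = 6.15 nm, sd_y = 6.25 nm
#>   CRLB precision:    6.41 nm

# truth, expressed in each frame's rendering-window coordinates
true_win <- cbind(mov$seeds$true_x_nm - mov$seeds$origin_x_px * 80,
                  mov$seeds$true_y_nm - mov$seeds$origin_y_px * 80)
errs <- sapply(seq_len(300), function(t)
  c(fits[[t]]$params$mu_x, fits[[t]]$params$mu_y) - true_win[t, ])
sds <- sapply(fits, function(f) c(f$precision_x, f$precision_y))
c(rms_true = sqrt(mean(errs^2)), rms_estimated = sqrt(mean(sds^2)))
#>      rms_true rms_estimated
#>      6.330241      6.342427
```

The per-spot Laplace estimates reproduce the true root-mean-square error to
a fraction of a nanometre — each spot knows how good it is. Those
precisions then feed the tracking layer:

```r
set.seed(5)
tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1),
                       A = matrix(c(.97, .03, .03, .97), 2),
                       pi0 = c(.5, .5), dt = 0.005,
                       sh = shutter("continuous"),
                       eps = function(s) runif(length(s), 20, 60),
                       n_frames = 1000)
fit <- vem_fit(tr[[1]]$obs, K = 2)
round(fit$D, 4)                         # um^2/s, states sorted ascending
#> [1] 0.1163 1.0876
misclassification(classify(fit), tr[[1]]$states, true_D = c(0.1, 1))
#> [1] 0.064
```

A command-line interface over the same functions lives in
`inst/cli/locprec.R` with subcommands `simulate`, `localize`, `diffusion`,
`hmm` and `refine`; see the script header for usage.

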