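# Shared fixtures, generated in code. Expensive batches are computed once
# per session and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

default_cam <- function() camera_model(gain = 50, offset = 100,
                                       readout_sd = 10, pixel_size = 80)

# render a batch of in-focus moving spots and MAP/MLE-fit them; returns
# per-spot signed errors (both axes), estimated precisions and fits
localized_batch <- function(n_spots, photons = 600, background = 1,
                            frame_interval = 0.001, mode = "map",
                            seed = 42, key = NULL) {
  if (!is.null(key) && !is.null(.fixture_cache[[key]]))
    return(.fixture_cache[[key]])
  set.seed(seed)
  scn <- sim_scenario(D = 1, frame_interval = frame_interval,
                      photons = photons, background = background,
                      z_script = 0)
  truth <- simulate_path(scn, n_spots)
  mov <- render_movie(scn, truth)
  pr <- prior_config(sigma0 = scn$sigma0)
  errs <- matrix(NA_real_, n_spots, 2)
  sds <- matrix(NA_real_, n_spots, 2)
  sigmas <- rep(NA_real_, n_spots)
  fits <- vector("list", n_spots)
  for (t in seq_len(n_spots)) {
    ex <- extract_roi(mov$stack[, , t],
                      c(mov$seeds$x_px[t], mov$seeds$y_px[t]), 9L)
    f <- fit_spot(ex$roi, scn$cam, mode = mode, priors = pr,
                  init = ex$seed_in_roi, roi_origin = ex$origin)
    fits[[t]] <- f
    if (f$converged && f$hessian_ok) {
      # truth in the coordinates of the rendered window
      true_nm <- c(mov$seeds$true_x_nm[t], mov$seeds$true_y_nm[t]) -
        c(mov$seeds$origin_x_px[t], mov$seeds$origin_y_px[t]) *
          scn$cam$pixel_size
      errs[t, ] <- c(f$params$mu_x, f$params$mu_y) - true_nm
      sds[t, ] <- c(f$precision_x, f$precision_y)
      sigmas[t] <- f$params$sigma
    }
  }
  out <- list(errs = errs, sds = sds, sigmas = sigmas, fits = fits,
              scn = scn, ok = stats::complete.cases(errs))
  if (!is.null(key)) .fixture_cache[[key]] <- out
  out
}

# the main calibration batch shared by acceptance and property tests
calibration_batch <- function() {
  localized_batch(2000, seed = 42, key = "map2000")
}

# trapezoid normalization of the count density over a wide grid
density_norm <- function(E, cam, step = 0.5) {
  hi <- max(4000, cam$gain * E * 3 + 12 * cam$readout_sd)
  cs <- seq(-12 * cam$readout_sd, hi, by = step)
  pracma::trapz(cs, exp(log_pcount(cs, E, cam)))
}
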