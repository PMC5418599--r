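# MLE/MAP spot fitting, Laplace and CRLB precision, filtering and the
# calibration-curve utility.

test_that("MAP and MLE objectives differ exactly by the log prior", {
  cam <- default_cam()
  set.seed(12)
  p <- spot_params(mu_x = 360, mu_y = 380, N = 500, b = 1, sigma = 100)
  roi <- sample_counts(pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80)),
                       cam)
  pr <- prior_config(sigma0 = 95.85, log_background_center = log(1))
  for (i in 1:5) {
    th <- c(runif(2, 3, 6), log(runif(1, 0.5, 3)), log(runif(1, 200, 900)),
            log(runif(1, 0.2, 2)))
    ds <- exp(th[5])
    sigma_px <- 95.85 / 80 * (1 + ds)
    th_mle <- c(th[1:4], log(sigma_px))
    # independent arithmetic for -ln q0 in internal coordinates:
    # Exp(1) prior density on ds with ln(ds) Jacobian, normal on ln b
    nlq <- (ds - th[5]) +
      0.5 * ((th[3] - log(1)) / log(30))^2 + log(log(30)) +
      0.5 * log(2 * pi)
    diff <- neg_log_posterior(th, roi, cam, priors = pr) -
      neg_log_posterior(th_mle, roi, cam, priors = NULL)
    expect_equal(diff, nlq, tolerance = 1e-12)
  }
})

test_that("objective evaluation is deterministic", {
  cam <- default_cam()
  set.seed(13)
  p <- spot_params(mu_x = 360, mu_y = 380, N = 500, b = 1, sigma = 100)
  roi <- sample_counts(pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80)),
                       cam)
  th <- c(4.5, 4.7, 0, log(500), log(1.2))
  expect_identical(neg_log_posterior(th, roi, cam),
                   neg_log_posterior(th, roi, cam))
  expect_error(neg_log_posterior(th, roi * NA, cam), "non-finite")
})

test_that("MLE on a high-N noise-free model image recovers the generating
           parameters", {
  # counts set to their conditional means: position, amplitude and width
  # are recovered to ~1e-3 relative; the background keeps a sub-photon
  # offset because the skewed EM-cascade density has mean != per-pixel ML
  cam <- default_cam()
  p <- spot_params(mu_x = 350, mu_y = 390, N = 20000, b = 2, sigma = 100)
  E <- pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80))
  f <- fit_spot(cam$gain * E + cam$offset, cam, mode = "mle",
                init = c(350, 390) / 80)
  expect_true(f$converged)
  est <- coef(f)
  expect_equal(est[["mu_x"]], 350, tolerance = 1e-3)
  expect_equal(est[["mu_y"]], 390, tolerance = 1e-3)
  expect_equal(est[["N"]], 20000, tolerance = 1e-3)
  expect_equal(est[["sigma"]], 100, tolerance = 1e-3)
  expect_lt(abs(est[["b"]] - 2), 0.6)
})

test_that("bright focused spots localize to within 10 nm with MAP", {
  cam <- default_cam()
  set.seed(14)
  pr <- prior_config(sigma0 = 95.85)
  for (i in 1:5) {
    mu <- 80 * c(4.5, 4.5) + runif(2, -40, 40)
    p <- spot_params(mu_x = mu[1], mu_y = mu[2], N = 2000, b = 1,
                     sigma = 100)
    roi <- sample_counts(pixel_intensities(p,
                         roi_geometry(c(0, 0), 9, 9, 80)), cam)
    f <- fit_spot(roi, cam, mode = "map", priors = pr)
    expect_true(f$converged)
    expect_lt(sqrt(sum((c(f$params$mu_x, f$params$mu_y) - mu)^2)), 10)
  }
})

test_that("pure background yields a non-converged or filtered fit", {
  cam <- default_cam()
  set.seed(15)
  roi <- sample_counts(matrix(1, 9, 9), cam)
  pr <- prior_config(sigma0 = 95.85)
  f <- fit_spot(roi, cam, mode = "map", priors = pr)
  flags <- filter_fits(list(f))
  expect_true(!f$converged || !flags$retained[1])
})

test_that("numeric Hessian machinery is exact on quadratics", {
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  x0 <- c(1, -2, 0.5)
  f <- function(x) 0.5 * t(x - x0) %*% A %*% (x - x0)
  H <- numeric_hessian(function(x) as.numeric(f(x)), x0 + 0.3)
  expect_equal(H, A, tolerance = 1e-6)
  expect_equal(sqrt(diag(solve(H))), sqrt(diag(solve(A))), tolerance = 1e-6)
})

test_that("Laplace precision agrees with the CRLB in the Poisson-dominated
           regime", {
  cam <- camera_model(readout_sd = 1)
  set.seed(16)
  p <- spot_params(mu_x = 360, mu_y = 360, N = 3000, b = 0.1, sigma = 96)
  E <- pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80))
  ratios <- replicate(5, {
    f <- fit_spot(sample_counts(E, cam), cam, mode = "mle")
    mean(c(f$precision_x, f$precision_y)) / crlb_precision(p, cam)
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("Laplace position s.d. scales as 1/sqrt(N)", {
  cam <- camera_model(readout_sd = 1)
  sds <- vapply(c(400, 1600), function(N) {
    p <- spot_params(mu_x = 350, mu_y = 390, N = N, b = 0.01, sigma = 100)
    E <- pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80))
    f <- fit_spot(cam$gain * E + cam$offset, cam, mode = "mle",
                  init = c(350, 390) / 80)
    f$precision_x
  }, 0)
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.05)
})

test_that("laplace_precision reports all-parameter posterior s.d.", {
  cam <- default_cam()
  set.seed(17)
  p <- spot_params(mu_x = 360, mu_y = 380, N = 800, b = 1, sigma = 100)
  roi <- sample_counts(pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80)),
                       cam)
  f <- fit_spot(roi, cam, mode = "map", priors = prior_config(sigma0 = 95.85))
  ps <- laplace_precision(f)
  expect_named(ps, c("mu_x_nm", "mu_y_nm", "ln_b", "ln_N", "w"))
  expect_true(all(ps > 0))
  expect_equal(ps[["mu_x_nm"]], f$precision_x)
})

test_that("CRLB matches its zero-background limit and scalings", {
  cam <- default_cam()
  # b -> 0: var = 2 sigma_a^2 / N
  p <- spot_params(0, 0, N = 400, b = 1e-15, sigma = 95.85)
  sa2 <- 95.85^2 + 80^2 / 12
  # b = 1e-15 rather than 0: the sqrt(2*tau) term is not smooth at 0
  expect_equal(crlb_precision(p, cam), sqrt(2 * sa2 / 400),
               tolerance = 1e-6)
  expect_equal(crlb_precision(p, cam), 6.97, tolerance = 1e-3)
  # doubling N at b = 0 halves the variance exactly
  p2 <- spot_params(0, 0, N = 800, b = 1e-15, sigma = 95.85)
  expect_equal(crlb_precision(p2, cam)^2, crlb_precision(p, cam)^2 / 2,
               tolerance = 1e-6)
  # monotone in background
  sds <- vapply(c(0.1, 1, 3, 10), function(b)
    crlb_precision(spot_params(0, 0, N = 400, b = b, sigma = 95.85), cam), 0)
  expect_true(all(diff(sds) > 0))
  pa <- spot_params(0, 0, N = 400, b = 1, sigma1 = 90, sigma2 = 100)
  expect_error(crlb_precision(pa, cam), "symmetric")
})

fake_fit <- function(mu_px = c(4.5, 4.5), sd_px = 0.5, width_px = 1.5,
                     converged = TRUE, seed_px = c(4.5, 4.5)) {
  cam <- default_cam()
  a <- cam$pixel_size
  structure(list(params = spot_params(mu_px[1] * a, mu_px[2] * a, N = 500,
                                      b = 1, sigma = width_px * a),
                 precision_x = sd_px * a, precision_y = sd_px * a,
                 converged = converged, hessian_ok = converged,
                 model = "symmetric", cam = cam, seed_px = seed_px),
            class = "spot_fit")
}

test_that("filter_fits applies the four retention criteria", {
  fits <- list(
    fake_fit(),                                   # all criteria pass
    fake_fit(mu_px = c(9.5, 4.5)),                # 5 px from seed
    fake_fit(width_px = 9.5),                     # too wide
    fake_fit(sd_px = 17),                         # too uncertain
    fake_fit(converged = FALSE))
  flags <- filter_fits(fits)
  expect_equal(flags$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(flags$dist_ok[2])
  expect_false(flags$width_ok[3])
  expect_false(flags$sd_ok[4])
  expect_false(flags$converged[5])
  # a fit within 1 px displacement, 0.5 px sd, 1.5 px width is retained
  expect_true(filter_fits(list(fake_fit(mu_px = c(5.5, 4.5))))$retained)
})

test_that("conditional_rmse is calibrated, homogeneous and definitional", {
  set.seed(18)
  est_sd <- runif(1e5, 10, 60)
  errors <- rnorm(1e5, 0, est_sd)
  cr <- conditional_rmse(errors, est_sd)
  expect_true(nrow(cr) >= 5)
  expect_true(all(abs(cr$ratio - 1) < 0.05))
  # scaling errors by 2 scales every ratio by 2
  cr2 <- conditional_rmse(2 * errors, est_sd)
  expect_equal(cr2$ratio, 2 * cr$ratio, tolerance = 1e-12)
  # single bin: ratio is RMS(error)/mean(sd) by definition
  sd1 <- rep(20, 1000)
  e1 <- rnorm(1000, 0, 20)
  cr1 <- conditional_rmse(e1, sd1, min_count = 100)
  expect_equal(nrow(cr1), 1)
  expect_equal(cr1$ratio, sqrt(mean(e1^2)) / 20, tolerance = 1e-12)
  # empty input
  expect_equal(nrow(conditional_rmse(numeric(0), numeric(0))), 0)
})

test_that("asymmetric MAP fits recover elongated spots with widths above
           the diffraction limit", {
  set.seed(19)
  cam <- default_cam()
  pr <- prior_config(sigma0 = 95.85)
  p <- spot_params(mu_x = 360, mu_y = 380, N = 1500, b = 1,
                   sigma1 = 160, sigma2 = 105, phi = 0.6)
  E <- pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80))
  for (i in 1:3) {
    f <- fit_spot(sample_counts(E, cam), cam, mode = "map",
                  model = "asymmetric", priors = pr)
    expect_true(f$converged)
    w <- sort(c(f$params$sigma1, f$params$sigma2))
    expect_true(all(w > 95.85))            # structural for MAP
    expect_equal(w, c(105, 160), tolerance = 0.12)
    # orientation recovered modulo pi (principal axes are unordered, but
    # the larger width's axis should align with the generating phi)
    phi_hat <- if (f$params$sigma1 >= f$params$sigma2) f$params$phi
               else (f$params$phi + pi / 2)
    d <- abs(phi_hat - 0.6) %% pi
    expect_lt(min(d, pi - d), 0.25)
    expect_lt(sqrt((f$params$mu_x - 360)^2 + (f$params$mu_y - 380)^2), 15)
    ps <- laplace_precision(f)
    expect_length(ps, 7)
  }
})

test_that("the fitter's fast objective path matches the exported objective", {
  set.seed(20)
  cam <- default_cam()
  pr <- prior_config(sigma0 = 95.85, log_background_center = log(1))
  p <- spot_params(mu_x = 345, mu_y = 395, N = 500, b = 1, sigma = 100)
  roi <- sample_counts(pixel_intensities(p, roi_geometry(c(0, 0), 9, 9, 80)),
                       cam)
  f <- fit_spot(roi, cam, mode = "map", priors = pr)
  expect_equal(f$objective,
               neg_log_posterior(f$theta_internal, roi, cam, priors = pr),
               tolerance = 1e-10)
})
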