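# MLE / MAP spot fitting with the EMCCD likelihood, Laplace-approximation
# posterior precision, CRLB precision, and post-fit quality filtering.
#
# Internal optimization coordinates (pixel units):
#   (mu_x, mu_y,  ln b,  ln N,  w)        symmetric
#   (mu_x, mu_y,  ln b,  ln N,  w1, w2, phi)  asymmetric
# where w = ln sigma_px for MLE, and w = ln(delta_sigma) for MAP so that
# sigma = sigma0 * (1 + delta_sigma) > sigma0 is structural.

#' Prior configuration for MAP localization
#'
#' Physically motivated priors: an exponential prior on the dimensionless
#' excess spot width `delta_sigma = (sigma - sigma0)/sigma0` (mean 1 for the
#' symmetric model, mean 1/2 per principal width for the asymmetric model),
#' and a weak normal prior with s.d. `log(30)` on the log background
#' intensity. Position and amplitude keep flat priors.
#'
#' @param sigma0 Diffraction-limited spot width in nm (see [sigma0()]).
#' @param excess_width_mean Mean of the exponential excess-width prior;
#'   `NULL` selects the model default (1 symmetric, 1/2 per width asymmetric).
#' @param log_background_center Centre of the normal prior on
#'   `ln b` (b in photons/pixel); `NULL` means estimate from the ROI border
#'   at fit time.
#' @param log_background_sd S.d. of the log-background prior.
#'
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(sigma0, excess_width_mean = NULL,
                         log_background_center = NULL,
                         log_background_sd = log(30)) {
  stopifnot(sigma0 > 0, log_background_sd > 0)
  if (!is.null(excess_width_mean) && excess_width_mean <= 0)
    stop("prior_config: excess_width_mean must be > 0")
  structure(list(sigma0 = sigma0,
                 excess_width_mean = excess_width_mean,
                 log_background_center = log_background_center,
                 log_background_sd = log_background_sd),
            class = "prior_config")
}

# expected photon map at internal coordinates, pixel units
.theta_to_params_px <- function(theta, model, map, sigma0_px) {
  if (model == "symmetric") {
    sig <- if (map) sigma0_px * (1 + exp(theta[5])) else exp(theta[5])
    list(mu_x = theta[1], mu_y = theta[2], b = exp(theta[3]),
         N = exp(theta[4]), sigma = sig)
  } else {
    if (map) {
      s1 <- sigma0_px * (1 + exp(theta[5]))
      s2 <- sigma0_px * (1 + exp(theta[6]))
    } else {
      s1 <- exp(theta[5]); s2 <- exp(theta[6])
    }
    list(mu_x = theta[1], mu_y = theta[2], b = exp(theta[3]),
         N = exp(theta[4]), sigma1 = s1, sigma2 = s2, phi = theta[7])
  }
}

.params_px_to_E <- function(pp, nx, ny) {
  p <- if (!is.null(pp$sigma)) {
    spot_params(pp$mu_x, pp$mu_y, pp$N, pp$b, sigma = pp$sigma)
  } else {
    spot_params(pp$mu_x, pp$mu_y, pp$N, pp$b,
                sigma1 = pp$sigma1, sigma2 = pp$sigma2, phi = pp$phi)
  }
  pixel_intensities(p, roi_geometry(c(0, 0), nx, ny, pixel_size = 1))
}

# separable expected-photon map for the symmetric model, pixel units;
# matches pixel_intensities() (same tensor Gauss-Legendre rule) but avoids
# the 2-D grid
.emap_sym_px <- function(pp, nx, ny, gl) {
  s <- pp$sigma
  fx <- .axis_integrals(pp$mu_x, s, nx, gl)
  fy <- .axis_integrals(pp$mu_y, s, ny, gl)
  pp$b + pp$N * outer(fy, fx)
}

.axis_integrals <- function(mu, s, n, gl) {
  nodes <- as.numeric(outer(gl$x, seq_len(n) - 1, "+"))
  d <- (nodes - mu) / s
  v <- exp(-0.5 * d * d) / (s * sqrt(2 * pi))
  colSums(matrix(rep(gl$w, n) * v, nrow = length(gl$x)))
}

# -ln q0 in internal coordinates (includes the ln(delta_sigma) Jacobian of the
# exponential prior; the background prior is a density on ln b directly)
.neg_log_prior <- function(theta, model, priors) {
  ewm <- priors$excess_width_mean
  if (model == "symmetric") {
    if (is.null(ewm)) ewm <- 1
    ds <- exp(theta[5])
    nlp <- log(ewm) + ds / ewm - theta[5]
  } else {
    if (is.null(ewm)) ewm <- 0.5
    ds <- exp(theta[5:6])
    nlp <- sum(log(ewm) + ds / ewm - theta[5:6])
  }
  c0 <- priors$log_background_center
  sd <- priors$log_background_sd
  nlp + 0.5 * ((theta[3] - c0) / sd)^2 + log(sd) + 0.5 * log(2 * pi)
}

#' Negative log-posterior of a spot model on a count ROI
#'
#' The objective minimized by [fit_spot()]: the negative EMCCD log-likelihood
#' of the offset-subtracted ROI counts under the pixel-integrated Gaussian
#' spot model, minus the log prior density expressed in the internal
#' coordinates (including change-of-variables terms). With `priors = NULL`
#' this is the pure negative log-likelihood (MLE objective, width coordinate
#' `ln sigma_px`); with a [prior_config()] it is the MAP objective (width
#' coordinate `ln delta_sigma`).
#'
#' @param theta Internal coordinate vector (see Details in [fit_spot()]).
#' @param roi Count matrix (offset *not* subtracted).
#' @param cam A [camera_model()].
#' @param priors A [prior_config()] or `NULL` for MLE.
#' @param model `"symmetric"` or `"asymmetric"`.
#'
#' @return Scalar objective value.
#' @export
neg_log_posterior <- function(theta, roi, cam, priors = NULL,
                              model = c("symmetric", "asymmetric")) {
  model <- match.arg(model)
  if (any(!is.finite(roi))) stop("neg_log_posterior: non-finite ROI values")
  map <- !is.null(priors)
  sigma0_px <- if (map) priors$sigma0 / cam$pixel_size else NA_real_
  pp <- .theta_to_params_px(theta, model, map, sigma0_px)
  E <- .params_px_to_E(pp, ncol(roi), nrow(roi))
  nll <- -sum(log_pcount(roi - cam$offset, E, cam))
  if (map) nll <- nll + .neg_log_prior(theta, model, priors)
  nll
}

# central-difference Hessian, step in internal coordinates
#' Numerical Hessian by central finite differences
#'
#' @param f Scalar function of a numeric vector.
#' @param x Point at which to differentiate.
#' @param step Finite-difference step (scalar or per-coordinate).
#'
#' @return Symmetric matrix of second derivatives.
#' @export
numeric_hessian <- function(f, x, step = 1e-4) {
  p <- length(x)
  h <- rep_len(step, p)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- rep(0, p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit a Gaussian spot to a count ROI
#'
#' Quasi-Newton (BFGS) minimization of [neg_log_posterior()] from a seed
#' position, followed by a Laplace approximation of the posterior: the
#' Hessian at the optimum is computed by central finite differences
#' (step 1e-4 in internal coordinates) and inverted to give the posterior
#' covariance; the reported per-axis position precisions are the marginal
#' standard deviations from the full inverse Hessian, in nm.
#'
#' @param roi Count matrix (camera counts, offset included), default 9 x 9.
#' @param cam A [camera_model()].
#' @param mode `"map"` (default) or `"mle"`.
#' @param model `"symmetric"` or `"asymmetric"` Gaussian spot.
#' @param priors A [prior_config()]; required for MAP. For MLE it is only
#'   used (if given) to report the excess width of the fitted spot.
#' @param init Seed position `c(x_px, y_px)` in ROI pixel coordinates
#'   (0-based; the ROI centre is `c(ncol/2, nrow/2)`). Default: ROI centre.
#' @param roi_origin Pixel indices of the ROI's lower-left corner in the full
#'   frame, used to report absolute positions.
#'
#' @return An object of class `spot_fit` with elements `params`
#'   ([spot_params()] in nm, absolute frame coordinates), `delta_sigma`,
#'   `posterior_cov` (internal coordinates), `precision_x`, `precision_y`
#'   (nm), `crlb_sd` (nm, symmetric model), `converged`, `hessian_ok`,
#'   `loglik_at_max`, and bookkeeping fields.
#' @export
fit_spot <- function(roi, cam, mode = c("map", "mle"),
                     model = c("symmetric", "asymmetric"),
                     priors = NULL, init = NULL, roi_origin = c(0, 0)) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  stopifnot(is.matrix(roi), inherits(cam, "camera_model"))
  if (any(!is.finite(roi))) stop("fit_spot: non-finite ROI values")
  nx <- ncol(roi); ny <- nrow(roi)
  a <- cam$pixel_size
  if (mode == "map" && is.null(priors))
    stop("fit_spot: MAP mode requires a prior_config()")
  map <- mode == "map"

  # seeds: ROI centre position, border-median background, photon-sum amplitude
  if (is.null(init)) init <- c(nx / 2, ny / 2)
  border <- c(roi[1, ], roi[ny, ], roi[, 1], roi[, nx])
  b0 <- max((stats::median(border) - cam$offset) / cam$gain, 0.05)
  N0 <- max(sum(roi - cam$offset) / cam$gain - b0 * nx * ny, 10)
  sigma0_px <- if (!is.null(priors)) priors$sigma0 / a else NA_real_
  if (map) {
    w0 <- log(0.5)
  } else {
    w0 <- log(if (is.finite(sigma0_px)) 1.5 * sigma0_px else 1.2)
  }
  theta0 <- c(init[1], init[2], log(b0), log(N0), w0)
  if (model == "asymmetric") theta0 <- c(theta0, w0, 0)

  pr <- priors
  if (map && is.null(pr$log_background_center))
    pr$log_background_center <- log(b0)
  # hot path: count-dependent likelihood structures are fixed within a fit
  loglik_fn <- .make_count_loglik(roi - cam$offset, cam)
  gl <- .gauss_legendre01(5L)
  obj <- function(th) {
    v <- tryCatch({
      pp <- .theta_to_params_px(th, model, map, sigma0_px)
      E <- if (model == "symmetric")
        .emap_sym_px(pp, nx, ny, gl)
      else .params_px_to_E(pp, nx, ny)
      nll <- -loglik_fn(as.numeric(E))
      if (map) nll <- nll + .neg_log_prior(th, model, pr)
      nll
    }, error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }

  opt <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value)
  theta <- if (!is.null(opt)) opt$par else theta0

  pp <- .theta_to_params_px(theta, model, map, sigma0_px)
  # physical-unit parameters, absolute frame coordinates
  params <- if (model == "symmetric") {
    spot_params((roi_origin[1] + pp$mu_x) * a, (roi_origin[2] + pp$mu_y) * a,
                pp$N, pp$b, sigma = pp$sigma * a)
  } else {
    spot_params((roi_origin[1] + pp$mu_x) * a, (roi_origin[2] + pp$mu_y) * a,
                pp$N, pp$b, sigma1 = pp$sigma1 * a, sigma2 = pp$sigma2 * a,
                phi = pp$phi)
  }
  delta_sigma <- if (!is.null(priors)) {
    if (model == "symmetric") params$sigma / priors$sigma0 - 1
    else c(params$sigma1, params$sigma2) / priors$sigma0 - 1
  } else NA_real_

  # Laplace approximation at the optimum
  posterior_cov <- NULL
  hessian_ok <- FALSE
  precision_x <- precision_y <- NA_real_
  if (converged) {
    H <- numeric_hessian(obj, theta, step = 1e-4)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(ch)) {
      posterior_cov <- chol2inv(ch)
      hessian_ok <- TRUE
      precision_x <- sqrt(posterior_cov[1, 1]) * a
      precision_y <- sqrt(posterior_cov[2, 2]) * a
    }
  }

  crlb_sd <- if (model == "symmetric")
    crlb_precision(params, cam) else NA_real_

  # pure log-likelihood at the optimum (no prior terms)
  Emap <- .params_px_to_E(pp, nx, ny)
  loglik <- sum(log_pcount(roi - cam$offset, Emap, cam))

  structure(list(params = params, delta_sigma = delta_sigma,
                 theta_internal = theta, posterior_cov = posterior_cov,
                 precision_x = precision_x, precision_y = precision_y,
                 crlb_sd = crlb_sd, converged = converged,
                 hessian_ok = hessian_ok, loglik_at_max = loglik,
                 objective = if (!is.null(opt)) opt$value else NA_real_,
                 mode = mode, model = model, cam = cam,
                 seed_px = roi_origin + init, roi_origin = roi_origin,
                 roi_dim = c(ny, nx), sigma0 = priors$sigma0),
            class = "spot_fit")
}

#' Laplace-approximation precision of a fitted spot
#'
#' Posterior standard deviations of all fit parameters from the inverse
#' Hessian at the optimum; position entries converted to nm.
#'
#' @param fit A converged [fit_spot()] result.
#'
#' @return Named vector of posterior s.d.; position entries in nm, scale
#'   parameters on their internal log scales.
#' @export
laplace_precision <- function(fit) {
  stopifnot(inherits(fit, "spot_fit"))
  if (!isTRUE(fit$converged)) stop("laplace_precision: fit did not converge")
  if (!isTRUE(fit$hessian_ok))
    stop("laplace_precision: Hessian not positive definite; no s.d. reported")
  sds <- sqrt(diag(fit$posterior_cov))
  a <- fit$cam$pixel_size
  sds[1:2] <- sds[1:2] * a
  nm <- if (fit$model == "symmetric")
    c("mu_x_nm", "mu_y_nm", "ln_b", "ln_N", "w")
  else c("mu_x_nm", "mu_y_nm", "ln_b", "ln_N", "w1", "w2", "phi")
  stats::setNames(sds, nm)
}

#' CRLB localization precision (symmetric Gaussian spot)
#'
#' Analytic approximation to the Cramer-Rao lower bound on the position s.d.
#' for a symmetric Gaussian spot on uniform background, with
#' `sigma_a^2 = sigma^2 + a^2/12`, `tau = 2*pi*sigma_a^2*b/(N*a^2)`, and an
#' overall factor 2 on the variance for EMCCD excess noise:
#' `var = 2*(sigma_a^2/N) * (1 + 4*tau + sqrt(2*tau/(1+4*tau)))`.
#'
#' @param p A symmetric [spot_params()] (lengths in nm), or a `spot_fit`.
#' @param cam A [camera_model()].
#'
#' @return Position s.d. in nm.
#' @examples
#' crlb_precision(spot_params(0, 0, N = 400, b = 1e-12, sigma = 95.85),
#'                camera_model())  # ~ 6.97 nm as b -> 0
#' @export
crlb_precision <- function(p, cam) {
  if (inherits(p, "spot_fit")) {
    cam <- p$cam
    p <- p$params
  }
  stopifnot(inherits(p, "spot_params"), inherits(cam, "camera_model"))
  if (p$model != "symmetric")
    stop("crlb_precision: only the symmetric spot model is supported")
  a <- cam$pixel_size
  sa2 <- p$sigma^2 + a^2 / 12
  tau <- 2 * pi * sa2 * p$b / (p$N * a^2)
  sqrt(2 * (sa2 / p$N) * (1 + 4 * tau + sqrt(2 * tau / (1 + 4 * tau))))
}

#' Post-fit quality filtering
#'
#' Applies the four retention criteria to a list of spot fits: the fit
#' converged, lies at most 4 pixels (Euclidean) from its reference position,
#' has estimated position uncertainties below 16 pixels on both axes, and a
#' spot width below 9 pixels (largest principal width for the asymmetric
#' model).
#'
#' @param fits List of `spot_fit` objects.
#' @param seeds Optional matrix/data.frame of reference positions
#'   (`x_px`, `y_px`, absolute frame pixels; ground truth when available).
#'   Default: each fit's own seed.
#'
#' @return A data.frame with one row per fit: logical columns `converged`,
#'   `dist_ok`, `sd_ok`, `width_ok`, `retained`, plus `dist_px`. Per-criterion
#'   pass counts are attached as attribute `"counts"`.
#' @export
filter_fits <- function(fits, seeds = NULL) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "spot_fit")))
  n <- length(fits)
  if (is.null(seeds)) {
    seeds <- t(vapply(fits, function(f) f$seed_px, numeric(2)))
  } else {
    seeds <- as.matrix(seeds)
    stopifnot(nrow(seeds) == n, ncol(seeds) == 2)
  }
  res <- data.frame(converged = logical(n), dist_ok = logical(n),
                    sd_ok = logical(n), width_ok = logical(n),
                    retained = logical(n), dist_px = NA_real_)
  for (i in seq_len(n)) {
    f <- fits[[i]]
    a <- f$cam$pixel_size
    mu_px <- c(f$params$mu_x, f$params$mu_y) / a
    d <- sqrt(sum((mu_px - seeds[i, ])^2))
    wid <- if (f$model == "symmetric") f$params$sigma / a
           else max(f$params$sigma1, f$params$sigma2) / a
    sd_px <- max(f$precision_x, f$precision_y) / a
    res$converged[i] <- isTRUE(f$converged) && isTRUE(f$hessian_ok)
    res$dist_px[i] <- d
    res$dist_ok[i] <- d <= 4
    res$sd_ok[i] <- is.finite(sd_px) && sd_px < 16
    res$width_ok[i] <- wid < 9
  }
  res$retained <- res$converged & res$dist_ok & res$sd_ok & res$width_ok
  attr(res, "counts") <- colSums(res[c("converged", "dist_ok", "sd_ok",
                                       "width_ok", "retained")])
  res
}

#' Conditional RMSE calibration curve
#'
#' Bins localizations by their estimated precision and, per bin, compares the
#' root-mean-square true error against the mean estimated precision. A
#' perfectly calibrated precision estimator gives ratios of 1 in every bin.
#'
#' @param errors True localization errors (nm, signed or absolute).
#' @param est_sd Estimated precisions (nm), aligned with `errors`.
#' @param bin_width Bin width in nm.
#' @param min_count Minimum points per bin; smaller bins are omitted.
#'
#' @return data.frame with columns `bin_lo`, `bin_hi`, `n`, `rms_error`,
#'   `mean_sd`, `ratio`.
#' @export
conditional_rmse <- function(errors, est_sd, bin_width = 7.5,
                             min_count = 300) {
  stopifnot(length(errors) == length(est_sd), bin_width > 0)
  if (length(errors) == 0)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), rms_error = numeric(0),
                      mean_sd = numeric(0), ratio = numeric(0)))
  idx <- floor(est_sd / bin_width)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(k) {
    sel <- idx == k
    data.frame(bin_lo = k * bin_width, bin_hi = (k + 1) * bin_width,
               n = sum(sel),
               rms_error = sqrt(mean(errors[sel]^2)),
               mean_sd = mean(est_sd[sel]))
  }))
  out <- out[out$n >= min_count, , drop = FALSE]
  out$ratio <- out$rms_error / out$mean_sd
  rownames(out) <- NULL
  out
}
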