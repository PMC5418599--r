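# S3 methods for the fitted-model classes.

#' @export
print.spot_params <- function(x, ...) {
  cat(sprintf("Gaussian spot (%s): mu = (%.1f, %.1f) nm, N = %.1f, b = %.3f\n",
              x$model, x$mu_x, x$mu_y, x$N, x$b))
  if (x$model == "symmetric") cat(sprintf("  sigma = %.1f nm\n", x$sigma))
  else cat(sprintf("  sigma1 = %.1f nm, sigma2 = %.1f nm, phi = %.3f rad\n",
                   x$sigma1, x$sigma2, x$phi))
  invisible(x)
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("Spot fit (%s, %s model)%s\n", toupper(x$mode), x$model,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  if (is.finite(x$precision_x))
    cat(sprintf("  Laplace precision: sd_x = %.2f nm, sd_y = %.2f nm\n",
                x$precision_x, x$precision_y))
  if (is.finite(x$crlb_sd))
    cat(sprintf("  CRLB precision:    %.2f nm\n", x$crlb_sd))
  invisible(x)
}

#' @export
coef.spot_fit <- function(object, ...) {
  p <- object$params
  if (object$model == "symmetric")
    c(mu_x = p$mu_x, mu_y = p$mu_y, N = p$N, b = p$b, sigma = p$sigma)
  else c(mu_x = p$mu_x, mu_y = p$mu_y, N = p$N, b = p$b,
         sigma1 = p$sigma1, sigma2 = p$sigma2, phi = p$phi)
}

#' @export
summary.spot_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$hessian_ok)) {
    cat("Posterior s.d. of all parameters:\n")
    print(round(laplace_precision(object), 4))
  }
  invisible(object)
}

#' Expected count image of a fitted spot
#'
#' @param object A `spot_fit`.
#' @param ... Unused.
#' @return Matrix of expected camera counts (offset included) over the
#'   fitted ROI.
#' @export
fitted.spot_fit <- function(object, ...) {
  a <- object$cam$pixel_size
  p <- object$params
  org <- object$roi_origin
  g <- roi_geometry(c(0, 0), object$roi_dim[2], object$roi_dim[1],
                    pixel_size = 1)
  pp <- if (object$model == "symmetric")
    spot_params(p$mu_x / a - org[1], p$mu_y / a - org[2], p$N, p$b,
                sigma = p$sigma / a)
  else spot_params(p$mu_x / a - org[1], p$mu_y / a - org[2], p$N, p$b,
                   sigma1 = p$sigma1 / a, sigma2 = p$sigma2 / a, phi = p$phi)
  pixel_intensities(pp, g) * object$cam$gain + object$cam$offset
}

#' @export
print.diffusive_hmm <- function(x, ...) {
  cat(sprintf("Diffusive HMM (%s variant), K = %d states\n", x$variant, x$K))
  cat(sprintf("  D (um^2/s): %s\n", paste(signif(x$D, 4), collapse = ", ")))
  if (x$K > 1) {
    cat("  transition matrix (per frame):\n")
    print(round(x$A, 4))
  }
  cat(sprintf("  blur constants: R = %.4g, tau = %.4g, beta = %.4g\n",
              x$R, x$tau, x$beta))
  cat(sprintf("  ELBO = %.4f after %d iterations%s\n", x$elbo, x$iterations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.diffusive_hmm <- function(object, ...) {
  list(D = object$D, A = object$A, pi = object$pi)
}

#' @export
summary.diffusive_hmm <- function(object, ...) {
  print(object)
  occ <- colMeans(object$posterior$gamma)
  cat("  mean state occupancy:", paste(signif(occ, 3), collapse = ", "), "\n")
  invisible(object)
}

#' @export
logLik.diffusive_hmm <- function(object, ...) {
  structure(object$elbo, class = "logLik",
            df = object$K + object$K * (object$K - 1),
            nobs = object$obs$n_frames)
}

#' Refined path from a fitted diffusive HMM
#'
#' `predict()` on a fitted model returns the posterior-refined positions
#' (see [refine_positions()]); with `newdata`, the posterior is recomputed
#' at the fitted parameters.
#'
#' @param object A `diffusive_hmm`.
#' @param newdata Optional [observations()].
#' @param ... Unused.
#' @export
predict.diffusive_hmm <- function(object, newdata = NULL, ...) {
  refine_positions(object, obs = newdata)
}

#' Simulate trajectories from a fitted diffusive HMM
#'
#' @param object A fitted `diffusive_hmm`.
#' @param nsim Number of trajectories.
#' @param seed Optional seed passed to `set.seed()`.
#' @param n_frames Frames per trajectory (default: as the fitted data).
#' @param eps Localization error s.d. (nm); default: RMS of the fitted
#'   data's precisions.
#' @param ... Unused.
#' @return As [synth_hmm_tracks()].
#' @export
simulate.diffusive_hmm <- function(object, nsim = 1, seed = NULL,
                                   n_frames = NULL, eps = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames)) n_frames <- object$obs$n_frames
  if (is.null(eps)) {
    eps <- if (!is.null(object$obs$v)) sqrt(mean(object$obs$v)) else 0
  }
  sh <- if (object$tau == 0 && object$beta == 0) shutter("instantaneous")
        else shutter("continuous")
  synth_hmm_tracks(object$K, object$D, object$A, object$pi, object$dt,
                   sh, eps, n_frames, n_traj = nsim)
}

#' Standardized observation residuals of a diffusive HMM
#'
#' Residuals `x_t - (1 - tau) E[y_t] - tau E[y_{t+1}]` divided by the
#' posterior-expected observation s.d. Because the posterior mean path
#' absorbs part of each observation, these are shrunk below unit scale
#' (as regression residuals are); gross departures from a roughly
#' Gaussian, sub-unit spread indicate misspecification.
#'
#' @param object A fitted `diffusive_hmm` (full or Kalman variant).
#' @param ... Unused.
#' @export
residuals.diffusive_hmm <- function(object, ...) {
  if (object$variant == "vbspt")
    stop("residuals: not defined for the displacement-only limit")
  obs <- object$obs
  ch <- object$posterior$chains
  g <- object$posterior$gamma
  T <- obs$n_frames
  i <- seq_len(T)
  tau <- object$tau
  out <- matrix(NA_real_, T, obs$n_axes)
  for (a in seq_len(obs$n_axes)) {
    m <- ch[[a]]$mean
    W <- as.numeric(g %*% (2 * object$D * 1e6 * object$dt * object$beta)) +
      obs$v[, a]
    out[, a] <- (obs$x[, a] - (1 - tau) * m[i] - tau * m[i + 1L]) / sqrt(W)
  }
  out
}

#' Plot state occupancy of a fitted diffusive HMM
#'
#' @param x A fitted `diffusive_hmm`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.diffusive_hmm <- function(x, ...) {
  g <- x$posterior$gamma
  graphics::matplot(seq_len(nrow(g)), g, type = "l", lty = 1,
                    xlab = "frame", ylab = "state probability",
                    ylim = c(0, 1), ...)
  invisible(x)
}
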