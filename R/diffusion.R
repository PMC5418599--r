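# Single-state diffusion estimation from camera-based trajectories:
# covariance-based estimators with and without localization-error
# information, exact-likelihood estimation with pointwise errors, and
# heuristic corrections for misspecified models.
#
# Under the camera observation model, measured steps dx_k = x_{k+1} - x_k are
# zero-mean Gaussian with
#   Var(dx_k)          = 2 D dt (1 - 2R) + 2 eps^2
#   Cov(dx_k, dx_{k+1}) = 2 D dt R - eps^2
# and uncorrelated at larger lags; R in [0, 1/4] is the shutter blur
# coefficient (1/6 for continuous illumination) and eps^2 the localization
# error variance (replaced by its average when errors vary).

#' Step-length moments of a trajectory
#'
#' Unbiased sample estimates of the mean-square step and the lag-1 step
#' covariance, pooled across axes.
#'
#' @param x Numeric vector (one axis) or matrix with one column per axis
#'   (positions, uniform time base).
#'
#' @return List of class `step_stats`: `msq` (mean square step), `lag1`
#'   (mean lagged product), `n_steps`, `n_pairs`, `n_axes`.
#' @examples
#' step_stats(c(0, 1, 2, 3))  # msq = 1, lag1 = 1
#' @export
step_stats <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("step_stats: need at least 3 positions")
  d <- diff(x)
  n <- nrow(d)
  msq <- mean(d^2)
  lag1 <- mean(d[-n, , drop = FALSE] * d[-1, , drop = FALSE])
  structure(list(msq = msq, lag1 = lag1, n_steps = n * ncol(d),
                 n_pairs = (n - 1) * ncol(d), n_axes = ncol(d)),
            class = "step_stats")
}

#' Covariance-based diffusion estimator (no precision information)
#'
#' Combines both step moments so that the blur coefficient and the
#' localization error variance cancel:
#' `D = msq/(2 dt) + lag1/dt`. Negative estimates are retained (not clamped)
#' so that ensemble means stay unbiased; they are flagged via the
#' `"negative"` attribute.
#'
#' @param stats A [step_stats()] (or a position vector/matrix, which is
#'   converted).
#' @param dt Time step, s.
#'
#' @return Diffusion estimate in (length unit)^2 per second.
#' @export
d_cov <- function(stats, dt) {
  if (!inherits(stats, "step_stats")) stats <- step_stats(stats)
  stopifnot(dt > 0)
  D <- stats$msq / (2 * dt) + stats$lag1 / dt
  attr(D, "negative") <- D < 0
  D
}

#' Covariance-based diffusion estimator using known precision
#'
#' When the mean localization error variance is known (e.g. from
#' Laplace-approximation precisions), the mean-square step alone yields the
#' improved estimator `D = (msq - 2*mean_eps2) / (2 dt (1 - 2R))`.
#'
#' @param stats A [step_stats()] (or positions).
#' @param dt Time step, s.
#' @param R Blur coefficient in `[0, 1/4]` (1/6 for continuous
#'   illumination).
#' @param mean_eps2 Mean localization error variance (same squared length
#'   unit as the positions).
#'
#' @return Diffusion estimate in (length unit)^2 per second.
#' @export
d_cov_eps <- function(stats, dt, R = 1 / 6, mean_eps2 = 0) {
  if (!inherits(stats, "step_stats")) stats <- step_stats(stats)
  stopifnot(dt > 0, R >= 0, R <= 0.25, mean_eps2 >= 0)
  D <- (stats$msq - 2 * mean_eps2) / (2 * dt * (1 - 2 * R))
  attr(D, "negative") <- D < 0
  D
}

#' Exact-likelihood diffusion estimation with pointwise errors
#'
#' Maximizes the exact Gaussian likelihood of the linear state-space form of
#' the camera observation model over the diffusion constant, using the
#' per-point localization error variances. This is the single-state case of
#' [vem_fit()]; it also returns the posterior mean path.
#'
#' @param x Position matrix (nm), one column per axis.
#' @param v Per-point localization error variances (nm^2), same shape as `x`
#'   (or a vector recycled across axes).
#' @param dt Time step, s.
#' @param sh A [shutter()] describing the exposure.
#'
#' @return List: `D` (um^2/s), `loglik`, `path` (posterior mean of the true
#'   positions, nm), `path_sd` (nm), `converged`.
#' @export
mle_diffusion <- function(x, v, dt, sh = shutter("continuous")) {
  x <- as.matrix(x)
  if (is.null(v)) stop("mle_diffusion: pointwise error variances required")
  v <- if (is.matrix(v)) v else matrix(v, nrow(x), ncol(x))
  stopifnot(nrow(v) == nrow(x), ncol(v) == ncol(x), all(v >= 0), dt > 0)
  bc <- blur_constants(sh)
  if (bc$tau == 0 && bc$beta == 0 && all(v == 0)) {
    # error-free instantaneous measurements: the ML estimate is the MSD
    # estimator in closed form and the path is observed exactly
    d <- diff(x)
    D_hat <- mean(d^2) / (2 * dt) / 1e6
    ll <- sum(stats::dnorm(d, 0, sqrt(2 * D_hat * 1e6 * dt), log = TRUE))
    return(list(D = D_hat, loglik = ll, path = x, path_sd = 0 * x,
                converged = TRUE))
  }
  if (bc$beta == 0 && any(v == 0))
    stop("mle_diffusion: zero error variances are singular when beta = 0")
  nll <- function(lnD) {
    D <- exp(lnD)
    -sum(vapply(seq_len(ncol(x)), function(a)
      .chain_loglik(x[, a], v[, a], D, dt, bc$tau, bc$beta), 0))
  }
  # bracket around the moment estimate
  D0 <- max(d_cov_eps(step_stats(x), dt, bc$R, mean(v)), 1e-6 * 1e6) / 1e6
  D0 <- max(D0, 1e-8)
  opt <- stats::optimize(nll, interval = log(D0) + c(-12, 8), tol = 1e-10)
  D_hat <- exp(opt$minimum)
  post <- lapply(seq_len(ncol(x)), function(a)
    .chain_posterior(x[, a], v[, a],
                     rep(1 / (2 * D_hat * 1e6 * dt), nrow(x)),
                     1 / (v[, a] + 2 * D_hat * 1e6 * dt * bc$beta),
                     bc$tau))
  path <- vapply(post, function(p) p$mean, numeric(nrow(x) + 1))
  path_sd <- vapply(post, function(p) sqrt(p$var), numeric(nrow(x) + 1))
  list(D = D_hat, loglik = -opt$objective, path = path, path_sd = path_sd,
       converged = is.finite(opt$objective))
}

#' Heuristic correction of diffusion estimates from simplified models
#'
#' Models that neglect motion blur (Kalman-type, `R = 0`) or both blur and
#' localization errors (vbSPT-type) absorb the neglected variance into their
#' fitted diffusion constant. Equating step-length variances with and
#' without those effects gives corrected estimates:
#' `kalman: D* = D_fit / (1 - 2R)`;
#' `vbspt: D* = (D_fit - mean_eps2 / dt) / (1 - 2R)`.
#'
#' @param D_fit Fitted diffusion constant (any units; `mean_eps2/dt` must
#'   match).
#' @param model `"kalman"` or `"vbspt"`.
#' @param R Blur coefficient of the true acquisition.
#' @param mean_eps2 Mean localization error variance.
#' @param dt Time step.
#'
#' @return Corrected diffusion constant.
#' @export
correct_D <- function(D_fit, model = c("kalman", "vbspt"), R = 1 / 6,
                      mean_eps2 = 0, dt = 1) {
  model <- match.arg(model)
  stopifnot(R >= 0, R <= 0.25, dt > 0, mean_eps2 >= 0)
  if (model == "kalman") D_fit / (1 - 2 * R)
  else (D_fit - mean_eps2 / dt) / (1 - 2 * R)
}
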