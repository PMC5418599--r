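# EMCCD noise model: high-gain electron-multiplication cascade plus Gaussian
# readout noise. Shared by the localizer (likelihood) and the simulator
# (count sampling).

# cache for quadrature nodes (order fixed at package level)
.locprec_cache <- new.env(parent = emptyenv())

#' EMCCD camera calibration
#'
#' Bundles the camera parameters needed by the count likelihood and the
#' simulator: electron-multiplication gain, ADC offset, readout noise and the
#' back-projected pixel size.
#'
#' @param gain EM gain, expected output electrons per detected photon
#'   (dimensionless, > 0).
#' @param offset ADC offset in camera counts, subtracted before any likelihood
#'   evaluation.
#' @param readout_sd Gaussian readout noise s.d. in counts (>= 0).
#' @param pixel_size Back-projected pixel size in nm (> 0).
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(gain = 50, readout_sd = 10, pixel_size = 80)
#' cam
#' @export
camera_model <- function(gain = 50, offset = 100, readout_sd = 10,
                         pixel_size = 80) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain),
            is.numeric(offset), length(offset) == 1L, is.finite(offset),
            is.numeric(readout_sd), length(readout_sd) == 1L,
            is.finite(readout_sd),
            is.numeric(pixel_size), length(pixel_size) == 1L,
            is.finite(pixel_size))
  if (gain <= 0) stop("camera_model: 'gain' must be > 0")
  if (readout_sd < 0) stop("camera_model: 'readout_sd' must be >= 0")
  if (pixel_size <= 0) stop("camera_model: 'pixel_size' must be > 0")
  structure(list(gain = gain, offset = offset, readout_sd = readout_sd,
                 pixel_size = pixel_size),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("EMCCD camera model\n")
  cat(sprintf("  EM gain:      %g e-/photon\n", x$gain))
  cat(sprintf("  offset:       %g counts\n", x$offset))
  cat(sprintf("  readout s.d.: %g counts\n", x$readout_sd))
  cat(sprintf("  pixel size:   %g nm\n", x$pixel_size))
  invisible(x)
}

# exponentially scaled modified Bessel function I_1(s) * exp(-s), s >= 0,
# by the Abramowitz & Stegun 9.8.3/9.8.4 polynomial approximations
# (relative error below ~1e-6; R's besselI serves as the oracle in tests
# but is an order of magnitude slower in the likelihood hot path)
.besseli1_scaled <- function(s) {
  out <- numeric(length(s))
  small <- s < 3.75
  if (any(small)) {
    ss <- s[small]
    t2 <- (ss / 3.75)^2
    p <- 0.5 + t2 * (0.87890594 + t2 * (0.51498869 + t2 * (0.15084934 +
         t2 * (0.02658733 + t2 * (0.00301532 + t2 * 0.00032411)))))
    out[small] <- ss * p * exp(-ss)
  }
  if (any(!small)) {
    sl <- s[!small]
    t <- 3.75 / sl
    p <- 0.39894228 + t * (-0.03988024 + t * (-0.00362018 + t * (0.00163801 +
         t * (-0.01031555 + t * (0.02282967 + t * (-0.02895312 +
         t * (0.01787654 - t * 0.00420059)))))))
    out[!small] <- p / sqrt(sl)
  }
  out
}

# log-density of the continuous branch of the high-gain EM output (before
# readout noise): n ~ Poisson(E) photons, each amplified by an Exponential
# electron count with mean `gain`; for n >= 1 the sum is Gamma(n, gain) and the
# mixture sums to sqrt(E/(x g)) exp(-E - x/g) I_1(2 sqrt(E x / g)) for x > 0.
# Uses the exponentially scaled Bessel function to stay finite at high counts.
.log_em_branch <- function(x, E, gain) {
  out <- rep(-Inf, length(x))
  ok <- x > 0 & E > 0
  if (any(ok)) {
    xo <- x[ok]
    Eo <- if (length(E) == 1L) E else E[ok]
    s <- 2 * sqrt(Eo * xo / gain)
    out[ok] <- -Eo - xo / gain + s +
      0.5 * (log(Eo) - log(xo) - log(gain)) +
      log(.besseli1_scaled(s))
  }
  out
}

#' Log-likelihood of offset-subtracted EMCCD counts
#'
#' Evaluates the log probability density of offset-subtracted pixel counts
#' under the high-gain EMCCD model: a Poisson number of photons, each
#' amplified by an exponentially distributed electron multiplication factor
#' (giving a zero-photon atom at zero plus a continuous Bessel-type branch),
#' convolved with zero-mean Gaussian readout noise. The convolution of the
#' continuous branch is evaluated by fixed-order Gauss-Legendre quadrature
#' over the amplified-electron variable, on the interval where the readout
#' Gaussian has support (the integrand is smooth there; the kink of the EM
#' density at zero can only fall on an interval endpoint). The zero-photon
#' atom contributes `exp(-E) * dnorm(c, 0, readout_sd)` analytically, so the
#' density is proper.
#'
#' @param counts Offset-subtracted pixel counts (numeric vector/matrix).
#' @param E Expected photons per pixel (>= 0); scalar or same shape as
#'   `counts`.
#' @param cam A [camera_model()].
#' @param order Quadrature order (>= 33).
#'
#' @return Log-density, same shape as `counts`; finite for all finite counts.
#' @examples
#' cam <- camera_model(gain = 50, readout_sd = 10)
#' log_pcount(0, E = 0, cam)  # pure readout Gaussian at its mode
#' @export
log_pcount <- function(counts, E, cam, order = 33L) {
  stopifnot(inherits(cam, "camera_model"))
  if (cam$readout_sd <= 0)
    stop("log_pcount: density evaluation requires readout_sd > 0")
  if (any(!is.finite(counts))) stop("log_pcount: non-finite counts")
  if (any(E < 0) || any(!is.finite(E))) stop("log_pcount: E must be >= 0")
  dm <- dim(counts)
  c_vec <- as.numeric(counts)
  E_vec <- if (length(E) == 1L) rep(as.numeric(E), length(c_vec)) else {
    if (length(E) != length(c_vec))
      stop("log_pcount: E must be scalar or match counts in length")
    as.numeric(E)
  }
  r <- cam$readout_sd
  gl <- .gauss_legendre01(as.integer(order))
  # integrate p_em(x) * phi(c - x) over the readout-Gaussian support
  span <- 9 * r
  lo <- pmax(0, c_vec - span)
  hi <- pmax(c_vec + span, 0)
  len <- hi - lo
  n <- length(c_vec)
  Q <- length(gl$x)
  lo_r <- rep(lo, each = Q)
  len_r <- rep(len, each = Q)
  xs <- lo_r + rep(gl$x, times = n) * len_r
  Es <- rep(E_vec, each = Q)
  dev <- rep(c_vec, each = Q) - xs
  lb <- .log_em_branch(xs, Es, cam$gain) -
    0.5 * log(2 * pi * r^2) - dev^2 / (2 * r^2) +
    rep(log(gl$w), times = n) + log(len_r)
  lb <- matrix(lb, nrow = Q)
  # log-sum-exp per column, plus the zero-photon atom
  m <- .col_max(lb)
  m[!is.finite(m)] <- 0
  cont <- m + log(colSums(exp(sweep(lb, 2, m, "-"))))
  cont[len <= 0] <- -Inf
  atom <- -E_vec + stats::dnorm(c_vec, 0, r, log = TRUE)
  hi_b <- pmax(cont, atom)
  out <- hi_b + log(exp(cont - hi_b) + exp(atom - hi_b))
  # guard: both branches can underflow far in the tails
  out[!is.finite(out)] <- -745
  if (!is.null(dm)) dim(out) <- dm
  out
}

.col_max <- function(M) {
  out <- M[1, ]
  for (i in seq_len(nrow(M))[-1]) out <- pmax(out, M[i, ])
  out
}

# factory for the per-ROI likelihood hot path: all count-dependent
# quadrature structures are fixed within a fit, so precompute them once and
# return a closure mapping an expected-photon vector to the summed
# log-likelihood of the (offset-subtracted) counts
.make_count_loglik <- function(counts, cam, order = 33L) {
  r <- cam$readout_sd
  gain <- cam$gain
  gl <- .gauss_legendre01(as.integer(order))
  c_vec <- as.numeric(counts)
  n <- length(c_vec)
  Q <- length(gl$x)
  span <- 9 * r
  lo <- pmax(0, c_vec - span)
  len <- pmax(c_vec + span, 0) - lo
  xs <- rep(lo, each = Q) + rep(gl$x, times = n) * rep(len, each = Q)
  dev <- rep(c_vec, each = Q) - xs
  # count-only part of the log integrand (readout Gaussian, weights, scale)
  base <- -0.5 * log(2 * pi * r^2) - dev^2 / (2 * r^2) +
    rep(log(gl$w), times = n) + log(rep(len, each = Q))
  xpos <- xs > 0
  lx <- numeric(length(xs))
  lx[xpos] <- 0.5 * (log(xs[xpos]) + log(gain)) + xs[xpos] / gain
  s_half <- numeric(length(xs))                 # sqrt(x/gain) term of s
  s_half[xpos] <- sqrt(xs[xpos] / gain)
  atom_base <- stats::dnorm(c_vec, 0, r, log = TRUE)
  idx <- which(xpos)
  base_lx <- base - lx          # -Inf pattern irrelevant: masked via idx
  s_half_i <- s_half[idx]
  # the continuous-branch integrand is evaluated without a log-sum-exp
  # shift: expected photons are strictly positive (b > 0) and the weighted
  # log-integrand is far from overflow, while underflow to 0 is harmless
  # because the zero-photon atom keeps the total density positive
  function(E_vec) {
    E_rep <- rep(E_vec, each = Q)
    Ei <- E_rep[idx]
    s <- 2 * sqrt(Ei) * s_half_i
    val <- rep(-Inf, length(base_lx))
    val[idx] <- base_lx[idx] - Ei + s + 0.5 * log(Ei) +
      log(.besseli1_scaled(s))
    cont_p <- colSums(matrix(exp(val), nrow = Q))
    dens <- cont_p + exp(-E_vec + atom_base)
    out <- log(dens)
    out[!is.finite(out)] <- -745
    sum(out)
  }
}

#' Sample EMCCD counts
#'
#' Draws per-pixel camera counts (offset included) from the same generative
#' model whose density [log_pcount()] evaluates: Poisson photon arrivals,
#' exponential EM amplification per photon (Gamma cascade), Gaussian readout
#' noise, plus the ADC offset. Reproducible under `set.seed()`.
#'
#' @param E_map Expected photons per pixel (vector, matrix or array; all
#'   >= 0).
#' @param cam A [camera_model()].
#'
#' @return Counts with the same shape as `E_map`.
#' @examples
#' cam <- camera_model()
#' set.seed(1)
#' mean(sample_counts(matrix(5, 100, 100), cam)) - cam$offset  # ~ gain * 5
#' @export
sample_counts <- function(E_map, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(E_map < 0) || any(!is.finite(E_map)))
    stop("sample_counts: E_map must be finite and >= 0")
  dm <- dim(E_map)
  E <- as.numeric(E_map)
  n_ph <- stats::rpois(length(E), E)
  x <- numeric(length(E))
  pos <- n_ph > 0L
  if (any(pos))
    x[pos] <- stats::rgamma(sum(pos), shape = n_ph[pos], scale = cam$gain)
  out <- x + stats::rnorm(length(E), 0, cam$readout_sd) + cam$offset
  if (!is.null(dm)) dim(out) <- dm
  out
}
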