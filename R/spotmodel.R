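# Gaussian spot intensity models (symmetric and asymmetric) and their
# pixel-integrated expected photon maps. All geometry follows the half-open
# pixel convention: pixel (i, j), 0-based, covers
# [i*a, (i+1)*a) x [j*a, (j+1)*a), centre at ((i+0.5)a, (j+0.5)a).

#' Gaussian spot parameters
#'
#' Parameters of a single-emitter Gaussian spot model over a constant
#' background. The symmetric model uses one width `sigma`; the asymmetric
#' model uses two principal widths `sigma1`, `sigma2` and a rotation angle
#' `phi` (interpreted modulo pi). The symmetric model is the asymmetric model
#' with equal principal widths.
#'
#' @param mu_x,mu_y Spot centre in nm.
#' @param N Expected photons per spot (> 0).
#' @param b Expected background photons per pixel (> 0).
#' @param sigma Spot width in nm (symmetric model, > 0).
#' @param sigma1,sigma2 Principal widths in nm (asymmetric model, > 0).
#' @param phi Rotation angle of the first principal axis, radians.
#'
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(mu_x, mu_y, N, b, sigma = NULL,
                        sigma1 = NULL, sigma2 = NULL, phi = 0) {
  stopifnot(is.finite(mu_x), is.finite(mu_y), is.finite(N), is.finite(b))
  if (N <= 0) stop("spot_params: N must be > 0")
  if (b <= 0) stop("spot_params: b must be > 0")
  if (!is.null(sigma)) {
    if (sigma <= 0) stop("spot_params: sigma must be > 0")
    out <- list(mu_x = mu_x, mu_y = mu_y, N = N, b = b,
                sigma = sigma, model = "symmetric")
  } else {
    if (is.null(sigma1) || is.null(sigma2))
      stop("spot_params: give either sigma, or sigma1 and sigma2")
    if (sigma1 <= 0 || sigma2 <= 0)
      stop("spot_params: principal widths must be > 0")
    out <- list(mu_x = mu_x, mu_y = mu_y, N = N, b = b,
                sigma1 = sigma1, sigma2 = sigma2,
                phi = phi %% pi, model = "asymmetric")
  }
  structure(out, class = "spot_params")
}

#' Region-of-interest geometry
#'
#' @param origin Integer pixel indices (x, y) of the lower-left ROI corner,
#'   0-based.
#' @param width,height ROI size in pixels (default 9 x 9).
#' @param pixel_size Pixel size in nm.
#'
#' @return An object of class `roi_geometry`.
#' @export
roi_geometry <- function(origin = c(0L, 0L), width = 9L, height = 9L,
                         pixel_size = 80) {
  stopifnot(length(origin) == 2L, width >= 1, height >= 1, pixel_size > 0)
  structure(list(origin = as.numeric(origin), width = as.integer(width),
                 height = as.integer(height), pixel_size = pixel_size),
            class = "roi_geometry")
}

# covariance matrix of the (possibly rotated) Gaussian profile, nm^2
.spot_cov <- function(p) {
  if (p$model == "symmetric") {
    diag(p$sigma^2, 2)
  } else {
    R <- matrix(c(cos(p$phi), sin(p$phi), -sin(p$phi), cos(p$phi)), 2, 2)
    R %*% diag(c(p$sigma1^2, p$sigma2^2)) %*% t(R)
  }
}

#' Pixel-integrated expected photon map
#'
#' Integrates the unit-normalized Gaussian spot profile over each pixel square
#' by tensor-product Gauss-Legendre quadrature (order 5 per axis) and returns
#' the expected photons per pixel, `E_ij = b + N * integral(pixel ij)`.
#'
#' @param p A [spot_params()] (lengths in nm).
#' @param g A [roi_geometry()].
#' @param gl_order Gauss-Legendre order per axis.
#'
#' @return Matrix of expected photons, `g$height` rows (y) by `g$width`
#'   columns (x); all entries > 0.
#' @examples
#' p <- spot_params(mu_x = 360, mu_y = 360, N = 500, b = 1, sigma = 100)
#' E <- pixel_intensities(p, roi_geometry())
#' sum(E - 1)  # ~ N for a well-contained spot
#' @export
pixel_intensities <- function(p, g, gl_order = 5L) {
  stopifnot(inherits(p, "spot_params"), inherits(g, "roi_geometry"))
  a <- g$pixel_size
  gl <- .gauss_legendre01(as.integer(gl_order))
  # quadrature nodes along each axis, grouped per pixel
  xn <- as.numeric(outer(gl$x, g$origin[1] + seq_len(g$width) - 1, "+")) * a
  yn <- as.numeric(outer(gl$x, g$origin[2] + seq_len(g$height) - 1, "+")) * a
  wx <- rep(gl$w, g$width)
  wy <- rep(gl$w, g$height)
  S <- .spot_cov(p)
  Si <- solve(S)
  dx <- xn - p$mu_x
  dy <- yn - p$mu_y
  norm_c <- 1 / (2 * pi * sqrt(S[1, 1] * S[2, 2] - S[1, 2]^2))
  # density on the tensor grid: exp(-(Si11 dx^2 + 2 Si12 dx dy + Si22 dy^2)/2)
  qx <- exp(-0.5 * Si[1, 1] * dx^2)
  qy <- exp(-0.5 * Si[2, 2] * dy^2)
  if (abs(S[1, 2]) < .Machine$double.eps * max(S)) {
    dens <- outer(qy * wy, qx * wx) * norm_c
  } else {
    cross <- exp(-Si[1, 2] * outer(dy, dx))
    dens <- outer(qy * wy, qx * wx) * cross * norm_c
  }
  # sum quadrature nodes within each pixel block; weights include the a^2 area
  m <- length(gl$x)
  block <- function(M) {
    M <- rowsum(M, rep(seq_len(nrow(M) / m), each = m))
    t(rowsum(t(M), rep(seq_len(ncol(M) / m), each = m)))
  }
  out <- p$b + p$N * a^2 * block(dens)
  dimnames(out) <- NULL
  out
}

.gauss_legendre01 <- function(order) {
  key <- paste0("gl", order)
  if (is.null(.locprec_cache[[key]])) {
    .locprec_cache[[key]] <- pracma::gaussLegendre(order, 0, 1)
  }
  .locprec_cache[[key]]
}

#' Diffraction-limited spot width
#'
#' Width of a focused spot, `0.21 * lambda / NA`, used as the physical lower
#' bound for the fitted spot width and as the scale of the excess-width prior.
#'
#' @param wavelength Emission wavelength in nm (> 0).
#' @param na Numerical aperture (> 0).
#'
#' @return Width in nm.
#' @examples
#' sigma0(639, 1.4)  # 95.85 nm
#' @export
sigma0 <- function(wavelength, na) {
  stopifnot(is.numeric(wavelength), is.numeric(na))
  if (any(wavelength <= 0) || any(na <= 0))
    stop("sigma0: wavelength and na must be > 0")
  0.21 * wavelength / na
}
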