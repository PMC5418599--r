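# Shutter functions and the blur constants they induce.
#
# A shutter is the normalized illumination/detection weight f(t) over one
# frame interval, represented on the unit interval (time in units of dt):
# either a piecewise-constant density on uniform bins, or a set of point
# atoms. Its cumulative S(t) determines the motion-blur coefficient
#   R = integral_0^1 S(t) (1 - S(t)) dt   (0 <= R <= 1/4),
# the first-moment coefficient tau = integral t f(t) dt, and the
# observation blur-variance coefficient beta = tau (1 - tau) - R used by the
# two-point observation embedding of the diffusive HMM. Both shutter classes
# admit exact (closed-form) integrals, so the canonical anchors are exact:
# continuous illumination R = 1/6, instantaneous R = 0, two end impulses
# R = 1/4.

#' Construct a shutter function
#'
#' @param type `"continuous"` (constant illumination over the frame),
#'   `"instantaneous"` (a single impulse at the start of the frame; the
#'   Kalman, no-blur limit), `"end_pulses"` (half the weight at each end of
#'   the frame; maximal blur coefficient), `"density"` (piecewise-constant
#'   density with `values` on uniform bins spanning the frame), or `"atoms"`
#'   (impulses of `weights` at `times`).
#' @param values Non-negative density values on uniform bins (for
#'   `"density"`); normalized internally.
#' @param times,weights Atom locations in `[0, 1]` (fraction of the frame
#'   interval) and non-negative weights (for `"atoms"`); weights normalized
#'   internally.
#'
#' @return An object of class `shutter`.
#' @examples
#' blur_constants(shutter("continuous"))   # R = 1/6
#' blur_constants(shutter("instantaneous")) # R = 0
#' @export
shutter <- function(type = c("continuous", "instantaneous", "end_pulses",
                             "density", "atoms"),
                    values = NULL, times = NULL, weights = NULL) {
  type <- match.arg(type)
  out <- switch(type,
    continuous = list(kind = "density", values = 1),
    instantaneous = list(kind = "atoms", times = 0, weights = 1),
    end_pulses = list(kind = "atoms", times = c(0, 1), weights = c(0.5, 0.5)),
    density = {
      if (is.null(values) || any(values < 0) || sum(values) <= 0)
        stop("shutter: 'values' must be non-negative with positive sum")
      list(kind = "density", values = values / mean(values))
    },
    atoms = {
      if (is.null(times) || is.null(weights) ||
          any(times < 0) || any(times > 1) ||
          any(weights < 0) || sum(weights) <= 0)
        stop("shutter: atoms need times in [0,1] and non-negative weights")
      o <- order(times)
      list(kind = "atoms", times = times[o],
           weights = weights[o] / sum(weights))
    })
  structure(out, class = "shutter")
}

#' Blur constants of a shutter
#'
#' Computes the motion-blur coefficient `R`, the first-moment coefficient
#' `tau`, and the observation blur-variance coefficient
#' `beta = tau * (1 - tau) - R` of a normalized shutter, by exact piecewise
#' integration of the cumulative shutter. For the state-space embedding
#' `x_t = (1 - tau) y_t + tau y_{t+1} + eta_t` with
#' `Var(eta_t) = eps_t^2 + 2 D dt beta`, these constants reproduce the
#' step-length covariances `Var(dx) = 2 D dt (1 - 2R) + 2 eps^2` and
#' `Cov(dx_k, dx_{k+1}) = 2 D dt R - eps^2` exactly.
#'
#' @param sh A [shutter()].
#'
#' @return List with elements `R` (in `[0, 1/4]`), `tau` (in `[0, 1]`) and
#'   `beta` (>= 0).
#' @export
blur_constants <- function(sh) {
  stopifnot(inherits(sh, "shutter"))
  if (sh$kind == "density") {
    v <- sh$values
    nb <- length(v)
    brk <- seq(0, 1, length.out = nb + 1)
    f <- v                       # density value per bin (mean 1)
    S <- c(0, cumsum(f) / nb)    # cumulative at bin edges, S linear inside
    seg <- function(S0, S1, len)
      len * ((S0 + S1) / 2 - (S0^2 + S0 * S1 + S1^2) / 3)
    R <- sum(seg(S[-(nb + 1)], S[-1], diff(brk)))
    tau <- sum(f * (brk[-1]^2 - brk[-(nb + 1)]^2) / 2)
  } else {
    t <- sh$times; w <- sh$weights
    S <- cumsum(w)               # S constant between atoms
    edges <- c(t, 1)
    lens <- diff(edges)
    R <- sum(S[seq_along(lens)] * (1 - S[seq_along(lens)]) * lens)
    if (t[1] > 0) R <- R + 0    # S = 0 before the first atom
    tau <- sum(w * t)
  }
  beta <- tau * (1 - tau) - R
  if (beta < -1e-12)
    stop("blur_constants: invalid shutter (beta < 0)")
  list(R = R, tau = tau, beta = max(beta, 0))
}

# discretize a shutter onto m midpoint atoms of one frame interval; used by
# the track simulator so that simulated moments match blur_constants() of the
# returned discrete shutter exactly
.discretize_shutter <- function(sh, m) {
  if (sh$kind == "atoms") return(sh)
  v <- sh$values
  mid <- (seq_len(m) - 0.5) / m
  # density values at midpoints (piecewise constant bins)
  bin <- pmin(floor(mid * length(v)) + 1, length(v))
  w <- v[bin]
  shutter("atoms", times = mid, weights = w)
}
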