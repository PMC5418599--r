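# Multi-state diffusive HMM with motion blur and pointwise localization
# errors, fitted by variational EM.
#
# Generative model (per axis, axes share the state sequence):
#   states   s_t, t = 1..T: Markov chain, transition A, initial pi
#   path     y_{t+1} = y_t + d_t,  d_t ~ N(0, 2 D_{s_t} dt)   (T+1 points)
#   obs      x_t = (1 - tau) y_t + tau y_{t+1} + eta_t,
#            Var(eta_t) = eps_t^2 + 2 D_{s_t} dt * beta
# The two-point observation embedding with (tau, beta) from blur_constants()
# reproduces the step-length covariances of the exposure-averaged camera
# model exactly for any normalized shutter. The state governing frame t's
# observation variance is the state of interval t -> t+1, during which the
# frame's photons are collected.
#
# Inference: factorized posterior q(s) q(y); discrete forward-backward for
# q(s), tridiagonal Gaussian message passing for q(y), closed-form M-steps
# for A and pi; D_k by exact 1-D maximization (closed form when beta = 0).

#' Observed trajectory with pointwise precisions
#'
#' @param x Position matrix, nm; one column per axis (typically 2), one row
#'   per frame; no gaps.
#' @param v Per-point localization error variances, nm^2; same shape as `x`,
#'   a vector recycled across axes, or `NULL` if unavailable (only the
#'   vbSPT-type limit can fit such data).
#' @param dt Frame interval, s.
#'
#' @return Object of class `observations`.
#' @export
observations <- function(x, v, dt) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, dt > 0, all(is.finite(x)))
  if (!is.null(v)) {
    v <- if (is.matrix(v)) v else matrix(v, nrow(x), ncol(x))
    stopifnot(nrow(v) == nrow(x), ncol(v) == ncol(x), all(v >= 0),
              all(is.finite(v)))
  }
  structure(list(x = x, v = v, dt = dt, n_frames = nrow(x),
                 n_axes = ncol(x)), class = "observations")
}

# ---- tridiagonal Gaussian chain ------------------------------------------

# posterior of y_1..y_{T+1} given per-interval path precisions p_t
# (= 1/(2 D dt) or its posterior expectation), per-frame observation
# precisions rho_t, and the two-point weight tau. Flat prior on y_1.
# Returns mean, marginal variances, lag-1 covariances and log det of the
# posterior precision matrix.
.chain_posterior <- function(x, v, p, rho, tau) {
  T <- length(x)
  n <- T + 1L
  c1 <- 1 - tau; c2 <- tau
  d <- numeric(n); e <- numeric(T); h <- numeric(n)
  idx <- seq_len(T)
  d[idx] <- p + rho * c1^2
  d[idx + 1L] <- d[idx + 1L] + p + rho * c2^2
  e[idx] <- -p + rho * c1 * c2
  h[idx] <- rho * x * c1
  h[idx + 1L] <- h[idx + 1L] + rho * x * c2
  # LDL^T factorization of the tridiagonal precision
  dd <- numeric(n); l <- numeric(T); z <- numeric(n)
  dd[1] <- d[1]; z[1] <- h[1]
  for (t in seq_len(T)) {
    l[t] <- e[t] / dd[t]
    dd[t + 1L] <- d[t + 1L] - e[t] * l[t]
    z[t + 1L] <- h[t + 1L] - l[t] * z[t]
  }
  m <- numeric(n); V <- numeric(n); C <- numeric(T)
  m[n] <- z[n] / dd[n]
  V[n] <- 1 / dd[n]
  for (t in rev(seq_len(T))) {
    m[t] <- z[t] / dd[t] - l[t] * m[t + 1L]
    C[t] <- -l[t] * V[t + 1L]
    V[t] <- 1 / dd[t] + l[t]^2 * V[t + 1L]
  }
  list(mean = m, var = V, cov = C, logdet = sum(log(dd)))
}

# exact marginal log-likelihood of one axis for a single diffusion constant
# (um^2/s), flat prior on y_1
.chain_loglik <- function(x, v, D_um, dt, tau, beta) {
  T <- length(x)
  Dn <- D_um * 1e6
  Vp <- rep(2 * Dn * dt, T)          # path interval variances, nm^2
  W <- v + 2 * Dn * dt * beta        # observation variances
  p <- 1 / Vp; rho <- 1 / W
  cp <- .chain_posterior(x, v, p, rho, tau)
  n <- T + 1L
  -T * log(2 * pi) - 0.5 * sum(log(Vp)) - 0.5 * sum(log(W)) -
    0.5 * sum(x^2 * rho) + 0.5 * n * log(2 * pi) - 0.5 * cp$logdet +
    0.5 * sum(cp$mean * .chain_mult(x, p, rho, tau, cp$mean, h_only = TRUE))
}

# returns h (the linear term) when h_only, so that h^T m can be formed
.chain_mult <- function(x, p, rho, tau, m, h_only = FALSE) {
  T <- length(x)
  c1 <- 1 - tau; c2 <- tau
  h <- numeric(T + 1L)
  idx <- seq_len(T)
  h[idx] <- rho * x * c1
  h[idx + 1L] <- h[idx + 1L] + rho * x * c2
  h
}

# expectations needed by the vEM from a chain posterior:
# E[(y_{t+1}-y_t)^2] and E[(x_t - (1-tau) y_t - tau y_{t+1})^2]
.chain_expectations <- function(cp, x, tau) {
  T <- length(x)
  i <- seq_len(T)
  m <- cp$mean; V <- cp$var; C <- cp$cov
  Edy2 <- (m[i + 1L] - m[i])^2 + V[i] + V[i + 1L] - 2 * C
  r <- x - (1 - tau) * m[i] - tau * m[i + 1L]
  Eres2 <- r^2 + (1 - tau)^2 * V[i] + tau^2 * V[i + 1L] +
    2 * tau * (1 - tau) * C
  list(Edy2 = Edy2, Eres2 = Eres2)
}

# ---- discrete forward-backward -------------------------------------------

.forward_backward <- function(lnphi, A, pi0) {
  T <- nrow(lnphi); K <- ncol(lnphi)
  mx <- apply(lnphi, 1, max)
  phi <- exp(lnphi - mx)
  alpha <- matrix(0, T, K); cvec <- numeric(T)
  a <- pi0 * phi[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  for (t in 2:T) {
    a <- as.numeric(alpha[t - 1, ] %*% A) * phi[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T, K)
  beta[T, ] <- 1
  xi <- array(0, c(T - 1, K, K))
  for (t in (T - 1):1) {
    pb <- phi[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- as.numeric(A %*% pb) / cvec[t + 1]
    w <- outer(alpha[t, ], pb) * A / cvec[t + 1]
    xi[t, , ] <- w
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(mx))
}

# entropy of the Markov-chain posterior q(s); uses sum_k xi_tjk = gamma_tj
# to avoid a time loop: H = -sum g1 ln g1 - sum xi ln xi + sum_{t<T} g ln g
.chain_entropy_s <- function(fb) {
  g1 <- fb$gamma[1, ]
  T1 <- dim(fb$xi)[1]
  xl <- fb$xi * log(fb$xi)
  gl <- fb$gamma[seq_len(T1), , drop = FALSE]
  gl <- gl * log(gl)
  -sum(g1 * log(g1), na.rm = TRUE) - sum(xl[is.finite(xl)]) +
    sum(gl[is.finite(gl)])
}

# ---- variational EM core --------------------------------------------------

.vem_core <- function(x, v, dt, K, tau, beta, D_init, A_init, pi_init,
                      max_iter = 1000L, tol = 1e-8, fixed_params = FALSE) {
  T <- nrow(x); Ax <- ncol(x)
  Dn <- D_init * 1e6
  A <- A_init; pi0 <- pi_init
  gamma <- matrix(1 / K, T, K)
  elbo_trace <- numeric(0)
  elbo <- -Inf
  cps <- vector("list", Ax)
  for (iter in seq_len(max_iter)) {
    # q(y): expected precisions under q(s)
    p_exp <- as.numeric(gamma %*% (1 / (2 * Dn * dt)))
    ex <- vector("list", Ax)
    for (a in seq_len(Ax)) {
      W <- outer(v[, a], 2 * Dn * dt * beta, "+")          # T x K
      rho_exp <- rowSums(gamma / W)
      cps[[a]] <- .chain_posterior(x[, a], v[, a], p_exp, rho_exp, tau)
      ex[[a]] <- .chain_expectations(cps[[a]], x[, a], tau)
    }
    # q(s): emission log-weights
    lnphi <- matrix(0, T, K)
    for (k in seq_len(K)) {
      Vp <- 2 * Dn[k] * dt
      acc <- 0
      for (a in seq_len(Ax)) {
        W <- v[, a] + 2 * Dn[k] * dt * beta
        acc <- acc - 0.5 * log(2 * pi * Vp) - ex[[a]]$Edy2 / (2 * Vp) -
          0.5 * log(2 * pi * W) - ex[[a]]$Eres2 / (2 * W)
      }
      lnphi[, k] <- acc
    }
    fb <- .forward_backward(lnphi, A, pi0)
    gamma <- fb$gamma
    # ELBO with the current q(y), q(s)
    Elnp <- sum(gamma * lnphi) +
      sum(gamma[1, ] * log(pmax(pi0, 1e-300))) +
      sum(matrix(apply(fb$xi, c(2, 3), sum), K, K) * log(pmax(A, 1e-300)))
    H_s <- .chain_entropy_s(fb)
    H_y <- sum(vapply(cps, function(cp)
      0.5 * ((T + 1) * (1 + log(2 * pi)) - cp$logdet), 0))
    new_elbo <- Elnp + H_s + H_y
    elbo_trace <- c(elbo_trace, new_elbo)
    done <- is.finite(elbo) &&
      abs(new_elbo - elbo) < tol * (abs(new_elbo) + 1e-10)
    elbo <- new_elbo
    if (done) break
    if (!fixed_params) {
      # M-step
      pi0 <- gamma[1, ]
      tr <- matrix(apply(fb$xi, c(2, 3), sum), K, K)
      A <- tr / pmax(rowSums(tr), 1e-300)
      for (k in seq_len(K)) {
        gk <- gamma[, k]
        sEdy2 <- sum(vapply(ex, function(e) sum(gk * e$Edy2), 0))
        if (beta == 0) {
          Dn[k] <- max(sEdy2 / (2 * dt * Ax * sum(gk)), 1e-12)
        } else {
          negq <- function(lnDn) {
            Dk <- exp(lnDn)
            val <- 0
            for (a in seq_len(Ax)) {
              W <- v[, a] + 2 * Dk * dt * beta
              val <- val + sum(gk * (0.5 * log(2 * Dk * dt) +
                                     ex[[a]]$Edy2 / (4 * Dk * dt) +
                                     0.5 * log(W) +
                                     ex[[a]]$Eres2 / (2 * W)))
            }
            val
          }
          ctr <- log(max(sEdy2 / (2 * dt * Ax * sum(gk)), 1e-12))
          Dn[k] <- exp(stats::optimize(negq, ctr + c(-8, 8),
                                       tol = 1e-7)$minimum)
        }
      }
    }
  }
  list(D = Dn / 1e6, A = A, pi = pi0, gamma = gamma, xi = fb$xi,
       chains = cps, elbo = elbo, elbo_trace = elbo_trace,
       iterations = iter, converged = iter < max_iter)
}

# displacement HMM (vbSPT-type limit): displacements are pure diffusion,
# no blur, no localization errors
.fit_displacement_hmm <- function(x, dt, K, D_init, A_init, pi_init,
                                  max_iter = 1000L, tol = 1e-8) {
  d <- diff(x)
  T <- nrow(d); Ax <- ncol(d)
  Dn <- D_init * 1e6
  A <- A_init; pi0 <- pi_init
  ll_trace <- numeric(0); ll <- -Inf
  for (iter in seq_len(max_iter)) {
    lnphi <- vapply(seq_len(K), function(k)
      rowSums(-0.5 * log(4 * pi * Dn[k] * dt) - d^2 / (4 * Dn[k] * dt)),
      numeric(T))
    fb <- .forward_backward(lnphi, A, pi0)
    ll_trace <- c(ll_trace, fb$loglik)
    done <- is.finite(ll) &&
      abs(fb$loglik - ll) < tol * (abs(fb$loglik) + 1e-10)
    ll <- fb$loglik
    if (done) break
    pi0 <- fb$gamma[1, ]
    tr <- matrix(apply(fb$xi, c(2, 3), sum), K, K)
    A <- tr / pmax(rowSums(tr), 1e-300)
    for (k in seq_len(K)) {
      gk <- fb$gamma[, k]
      Dn[k] <- max(sum(gk * rowSums(d^2)) / (2 * dt * Ax * sum(gk)), 1e-12)
    }
  }
  list(D = Dn / 1e6, A = A, pi = pi0, gamma = fb$gamma, xi = fb$xi,
       chains = NULL, elbo = ll, elbo_trace = ll_trace,
       iterations = iter, converged = iter < max_iter)
}

.sort_states <- function(res) {
  o <- order(res$D)
  res$D <- res$D[o]
  res$A <- res$A[o, o, drop = FALSE]
  res$pi <- res$pi[o]
  res$gamma <- res$gamma[, o, drop = FALSE]
  if (!is.null(res$xi)) res$xi <- res$xi[, o, o, drop = FALSE]
  res
}

#' Fit a multi-state diffusive HMM by variational EM
#'
#' Maximizes an evidence lower bound (ELBO) on the likelihood of the
#' blur-aware observation model (see the package vignette): a Brownian path
#' with state-dependent diffusion constant, exposure-averaged through the
#' shutter, observed with known per-frame localization error variances. Uses
#' a factorized posterior over the discrete state sequence and the
#' continuous path; the best of `restarts` jittered initializations is
#' returned, with states sorted by ascending diffusion constant.
#'
#' @param obs An [observations()] object (positions nm, variances nm^2).
#' @param K Number of diffusive states (>= 1).
#' @param sh A [shutter()]; determines the blur constants.
#' @param restarts Number of initializations: the first comes from a
#'   blur/noise-corrected displacement-HMM segmentation, the second is
#'   log-spaced around a moment estimate, further ones are jittered.
#' @param max_iter Maximum vEM iterations per restart.
#' @param tol Relative ELBO convergence tolerance.
#' @param D_init Optional initial diffusion constants (um^2/s, length K).
#' @param hops Rounds of basin hopping: refits from the incumbent solution
#'   with shrunk/grown diffusion constants, keeping the best ELBO.
#'
#' @return An object of class `diffusive_hmm`: per-state diffusion constants
#'   `D` (um^2/s, ascending), transition matrix `A` (per frame), initial
#'   distribution `pi`, blur constants `R`, `tau`, `beta`, the ELBO and its
#'   trace, and the posterior (`gamma`, `xi`, Gaussian path chains).
#' @export
vem_fit <- function(obs, K, sh = shutter("continuous"), restarts = 5L,
                    max_iter = 5000L, tol = 1e-8, D_init = NULL,
                    hops = 1L) {
  stopifnot(inherits(obs, "observations"), K >= 1,
            obs$n_frames >= K + 2)
  bc <- blur_constants(sh)
  .vem_dispatch(obs, K, bc, restarts, max_iter, tol, D_init,
                variant = "full", hops = hops)
}

.vem_dispatch <- function(obs, K, bc, restarts, max_iter, tol, D_init,
                          variant, hops = 1L) {
  x <- obs$x; v <- obs$v; dt <- obs$dt
  degenerate <- bc$tau == 0 && bc$beta == 0 &&
    (is.null(v) || all(v == 0))
  if (variant != "vbspt" && is.null(v))
    stop("vem_fit: pointwise precision variances (obs$v) are required; ",
         "fit the vbSPT-type limit for data without precisions")
  if (variant != "vbspt" && bc$beta == 0 && !degenerate && any(v == 0))
    stop("vem_fit: zero error variances are singular when beta = 0")
  use_displacement <- variant == "vbspt" || degenerate

  # initialization scale from the blur-corrected moment estimator
  ss <- step_stats(x)
  D_scale <- max(ss$msq / (2 * dt * 1e6), 1e-6)
  if (!is.null(v)) D_scale <- max(D_scale - mean(v) / (dt * 1e6), 1e-6)
  A_sticky <- matrix((1 - 0.95) / max(K - 1, 1), K, K)
  diag(A_sticky) <- if (K > 1) 0.95 else 1
  D_spread <- if (K == 1) D_scale
              else exp(seq(log(0.1), log(10), length.out = K)) * D_scale

  # first restart: initialize from a blur/noise-corrected displacement-HMM
  # fit, whose state segmentation is cheap and usually lands the vEM in the
  # right basin; second restart: log-spaced widths; further restarts jitter
  disp_init <- NULL
  if (!use_displacement && K > 1) {
    dres <- tryCatch(
      .fit_displacement_hmm(x, dt, K, D_spread, A_sticky, rep(1 / K, K),
                            max_iter = 300L, tol = 1e-9),
      error = function(e) NULL)
    if (!is.null(dres)) {
      Dcor <- (dres$D - mean(v) / (dt * 1e6)) / (1 - 2 * bc$R)
      disp_init <- list(D = sort(pmax(Dcor, 1e-4 * D_scale)),
                        A = dres$A[order(dres$D), order(dres$D)],
                        pi = pmax(dres$pi, 0.01))
      disp_init$pi <- disp_init$pi / sum(disp_init$pi)
    }
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    if (!is.null(D_init)) {
      D0 <- D_init; A0 <- A_sticky; pi0 <- rep(1 / K, K)
      if (r > 1) D0 <- D0 * exp(stats::rnorm(K, 0, 0.3))
    } else if (r == 1 && !is.null(disp_init)) {
      D0 <- disp_init$D; A0 <- disp_init$A; pi0 <- disp_init$pi
    } else if (r == 2 || is.null(disp_init)) {
      D0 <- D_spread; A0 <- A_sticky; pi0 <- rep(1 / K, K)
    } else {
      D0 <- disp_init$D * exp(stats::rnorm(K, 0, 0.3))
      A0 <- disp_init$A; pi0 <- disp_init$pi
    }
    res <- if (use_displacement) {
      .fit_displacement_hmm(x, dt, K, D0, A0, pi0, max_iter, tol)
    } else {
      .vem_core(x, v, dt, K, bc$tau, bc$beta, D0, A0, pi0, max_iter, tol)
    }
    if (is.null(best) || res$elbo > best$elbo) best <- res
    if (K == 1 && !is.null(D_init)) break
    if (K == 1 && r >= 2) break   # single-state fits have no label ambiguity
  }

  # basin hopping: the vEM objective has well-separated local optima in D
  # (soft state assignments inflate slow-state estimates); refit from the
  # incumbent with shrunk/grown diffusion constants and keep the best ELBO
  if (K > 1 && hops > 0) {
    hop_factors <- c(lapply(seq_len(K), function(k) {
      f <- rep(1, K); f[k] <- 0.6; f
    }), list(rep(0.6, K), rep(1.5, K)))
    for (round in seq_len(hops)) {
      improved <- FALSE
      for (f in hop_factors) {
        D0 <- pmax(best$D * f, 1e-8)
        pi0 <- pmax(best$pi, 1e-3); pi0 <- pi0 / sum(pi0)
        A0 <- (best$A + 1e-4) / rowSums(best$A + 1e-4)
        res <- if (use_displacement) {
          .fit_displacement_hmm(x, dt, K, D0, A0, pi0, max_iter, tol)
        } else {
          .vem_core(x, v, dt, K, bc$tau, bc$beta, D0, A0, pi0, max_iter,
                    tol)
        }
        if (res$elbo > best$elbo) {
          best <- res
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  best <- .sort_states(best)
  structure(list(K = K, D = best$D, A = best$A, pi = best$pi,
                 R = bc$R, tau = bc$tau, beta = bc$beta, dt = dt,
                 elbo = best$elbo, elbo_trace = best$elbo_trace,
                 iterations = best$iterations, converged = best$converged,
                 variant = variant,
                 posterior = list(gamma = best$gamma, xi = best$xi,
                                  chains = best$chains),
                 obs = obs),
            class = "diffusive_hmm")
}

#' Construct a diffusive HMM from known parameters
#'
#' Builds a `diffusive_hmm` object without fitting, e.g. to refine positions
#' under externally estimated or theoretical parameters, or to continue from
#' a stored model.
#'
#' @param D Diffusion constants, um^2/s (length K; need not be sorted).
#' @param A Per-frame transition matrix (default: identity).
#' @param pi0 Initial state distribution (default uniform).
#' @param dt Frame interval, s.
#' @param sh A [shutter()] (sets R, tau, beta).
#' @param variant `"full"` or `"kalman"`.
#'
#' @return A `diffusive_hmm` without posterior or data.
#' @export
diffusive_hmm_model <- function(D, A = NULL, pi0 = NULL, dt,
                                sh = shutter("continuous"),
                                variant = c("full", "kalman")) {
  variant <- match.arg(variant)
  K <- length(D)
  stopifnot(all(D > 0), dt > 0)
  if (is.null(A)) A <- diag(K)
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  stopifnot(nrow(A) == K, ncol(A) == K, all(abs(rowSums(A) - 1) < 1e-9),
            length(pi0) == K, abs(sum(pi0) - 1) < 1e-9)
  bc <- if (variant == "kalman") list(R = 0, tau = 0, beta = 0)
        else blur_constants(sh)
  o <- order(D)
  structure(list(K = K, D = D[o], A = A[o, o, drop = FALSE], pi = pi0[o],
                 R = bc$R, tau = bc$tau, beta = bc$beta, dt = dt,
                 elbo = NA_real_, elbo_trace = numeric(0),
                 iterations = 0L, converged = NA, variant = variant,
                 posterior = NULL, obs = NULL),
            class = "diffusive_hmm")
}

#' Simplified-model limits of the diffusive HMM
#'
#' `"kalman"`: models pointwise localization errors but not blur
#' (`tau = beta = R = 0`). `"vbspt"`: additionally neglects localization
#' errors, reducing to an HMM on raw displacements.
#'
#' @inheritParams vem_fit
#' @param variant `"kalman"` or `"vbspt"`.
#'
#' @return A `diffusive_hmm` (see [vem_fit()]).
#' @export
limit_fit <- function(obs, K, variant = c("kalman", "vbspt"),
                      restarts = 5L, max_iter = 5000L, tol = 1e-8,
                      D_init = NULL, hops = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "observations"), K >= 1, obs$n_frames >= K + 2)
  bc <- list(R = 0, tau = 0, beta = 0)
  .vem_dispatch(obs, K, bc, restarts, max_iter, tol, D_init, variant,
                hops = hops)
}

#' Most probable state per frame
#'
#' @param fit A fitted `diffusive_hmm`.
#'
#' @return Integer vector of per-frame states (1 = slowest), length equal to
#'   the number of frames (the vbSPT-type limit, defined on displacements,
#'   is padded by repeating its last interval state).
#' @export
classify <- function(fit) {
  stopifnot(inherits(fit, "diffusive_hmm"))
  s <- max.col(fit$posterior$gamma, ties.method = "first")
  if (fit$variant == "vbspt") s <- c(s, s[length(s)])
  s
}

#' Misclassification rate against a known state sequence
#'
#' States are compared after sorting by diffusion constant: supply `true_D`
#' to relabel the truth in ascending-D order (fitted states are already
#' sorted).
#'
#' @param pred Predicted states (from [classify()]).
#' @param truth True state sequence.
#' @param true_D Optional diffusion constants indexed by the truth labels.
#'
#' @return Fraction of mismatched frames.
#' @export
misclassification <- function(pred, truth, true_D = NULL) {
  if (!is.null(true_D)) truth <- rank(true_D)[truth]
  stopifnot(length(pred) == length(truth))
  mean(pred != truth)
}

#' Posterior refinement of measured positions
#'
#' Posterior mean and s.d. of the quantity each measurement estimates — the
#' shutter-averaged true position of the frame. Writing the exposure
#' average as the two-point combination `(1 - tau) y_t + tau y_{t+1}` plus
#' an independent intra-frame bridge deviation of variance
#' `sigma_b^2 = 2 D dt beta`, the refined estimate blends the posterior
#' path with the measurement itself:
#' `(1 - w) [(1 - tau) E[y_t] + tau E[y_{t+1}]] + w x_t` with
#' `w = sigma_b^2 / (sigma_b^2 + eps_t^2)`, and posterior variance
#' `(1 - w)^2 Var[(1 - tau) y_t + tau y_{t+1}] +
#'  sigma_b^2 eps_t^2 / (sigma_b^2 + eps_t^2)`.
#' Limits: a static emitter with equal errors gives the `eps/sqrt(n)`
#' averaging limit; `eps -> 0` returns the measured positions; a blur-free
#' shutter gives the pure path posterior. Refined s.d. is not guaranteed to
#' be below the raw precision per frame, but is on average, with the
#' largest gains for slow states with poor localizations.
#'
#' @param fit A fitted `diffusive_hmm` (full or Kalman variant).
#' @param obs Optional new [observations()]; default: the fitted data. With
#'   new data, the posterior is recomputed at fixed model parameters.
#'
#' @return data.frame: `frame`, then per axis `y<i>` (refined position, nm)
#'   and `sd<i>` (posterior s.d., nm).
#' @export
refine_positions <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "diffusive_hmm"))
  if (fit$variant == "vbspt")
    stop("refine_positions: the displacement-only limit has no path model")
  if (is.null(obs)) {
    if (is.null(fit$obs))
      stop("refine_positions: supply observations for a parameter-only model")
    obs <- fit$obs
    chains <- fit$posterior$chains
    gamma <- fit$posterior$gamma
  } else {
    stopifnot(inherits(obs, "observations"))
    chains <- NULL
  }
  if (is.null(chains)) {
    res <- .vem_core(obs$x, obs$v, obs$dt, fit$K, fit$tau, fit$beta,
                     fit$D, fit$A, fit$pi, max_iter = 100L, tol = 1e-10,
                     fixed_params = TRUE)
    chains <- res$chains
    gamma <- res$gamma
  }
  T <- obs$n_frames
  i <- seq_len(T)
  tau <- fit$tau
  # expected intra-frame bridge variance per frame (state-weighted)
  sb2 <- as.numeric(gamma %*% (2 * fit$D * 1e6 * obs$dt * fit$beta))
  out <- data.frame(frame = i)
  for (a in seq_len(obs$n_axes)) {
    cp <- chains[[a]]
    two_pt <- (1 - tau) * cp$mean[i] + tau * cp$mean[i + 1L]
    v_two <- (1 - tau)^2 * cp$var[i] + tau^2 * cp$var[i + 1L] +
      2 * tau * (1 - tau) * cp$cov
    eps2 <- obs$v[, a]
    w <- ifelse(sb2 + eps2 > 0, sb2 / (sb2 + eps2), 0)
    out[[paste0("y", a)]] <- (1 - w) * two_pt + w * obs$x[, a]
    vv <- (1 - w)^2 * v_two + ifelse(sb2 + eps2 > 0,
                                     sb2 * eps2 / (sb2 + eps2), 0)
    out[[paste0("sd", a)]] <- sqrt(pmax(vv, 0))
  }
  out
}

# ---- exact track-level generator -----------------------------------------

#' Simulate trajectories directly from the diffusive HMM
#'
#' Exact simulation of the generative model at the track level, bypassing
#' image rendering: a sub-stepped Brownian path with Markov state switching
#' at frame boundaries, exposure-averaged through the (discretized) shutter,
#' plus heteroscedastic Gaussian localization noise. The shutter is
#' discretized onto `substeps` midpoint atoms; the discrete shutter actually
#' simulated is attached as attribute `"shutter"` so its exact blur
#' constants can be recovered with [blur_constants()].
#'
#' @param K Number of states.
#' @param D Diffusion constants, um^2/s (length K).
#' @param A Per-frame transition matrix.
#' @param pi0 Initial state distribution.
#' @param dt Frame interval, s.
#' @param sh A [shutter()].
#' @param eps Localization error s.d. (nm): a scalar, a length-K vector
#'   (per state), or a function of the state sequence returning per-frame
#'   s.d. values.
#' @param n_frames Frames per trajectory.
#' @param n_traj Number of trajectories.
#' @param n_axes Number of axes (default 2).
#' @param substeps Path substeps per frame for shutter discretization.
#' @param state_script Optional fixed per-frame state sequence (overrides
#'   `A` and `pi0`).
#'
#' @return List of trajectories; each has `obs` ([observations()]),
#'   `states` (true per-frame states, indexing `D` as given), and `y_true`
#'   (noise-free exposure-averaged positions, nm).
#' @export
synth_hmm_tracks <- function(K, D, A = NULL, pi0 = NULL, dt, sh, eps,
                             n_frames, n_traj = 1L, n_axes = 2L,
                             substeps = 20L, state_script = NULL) {
  stopifnot(length(D) == K, all(D > 0), dt > 0, n_frames >= 2)
  if (is.null(state_script)) {
    stopifnot(!is.null(A), nrow(A) == K, ncol(A) == K,
              all(abs(rowSums(A) - 1) < 1e-9))
    if (is.null(pi0)) pi0 <- rep(1 / K, K)
  }
  dsh <- .discretize_shutter(sh, substeps)
  u <- dsh$times; w <- dsh$weights
  m <- length(u)
  Dn <- D * 1e6
  out <- vector("list", n_traj)
  for (j in seq_len(n_traj)) {
    s <- if (!is.null(state_script)) rep_len(state_script, n_frames)
    else {
      st <- integer(n_frames)
      st[1] <- sample.int(K, 1, prob = pi0)
      for (t in seq_len(n_frames - 1))
        st[t + 1] <- sample.int(K, 1, prob = A[st[t], ])
      st
    }
    # global atom times (units of dt) and state-weighted increment variances
    tg <- as.numeric(outer(u, seq_len(n_frames) - 1, "+"))
    cumD <- c(0, cumsum(Dn[s]))                    # integral of D over frames
    Cfun <- function(tt) {
      fl <- pmin(floor(tt), n_frames - 1)
      cumD[fl + 1] + Dn[s[fl + 1]] * (tt - fl)
    }
    Cg <- Cfun(tg)
    varinc <- 2 * dt * diff(Cg)
    ns <- length(tg)
    xmat <- matrix(NA_real_, n_frames, n_axes)
    ytrue <- matrix(NA_real_, n_frames, n_axes)
    eps_t <- if (is.function(eps)) eps(s)
             else if (length(eps) == K) eps[s]
             else rep_len(eps, n_frames)
    for (a in seq_len(n_axes)) {
      y <- c(0, cumsum(stats::rnorm(ns - 1, 0, sqrt(pmax(varinc, 0)))))
      ym <- matrix(y, m, n_frames)
      ytrue[, a] <- as.numeric(w %*% ym)
      xmat[, a] <- ytrue[, a] + stats::rnorm(n_frames, 0, eps_t)
    }
    out[[j]] <- list(obs = observations(xmat, matrix(eps_t^2, n_frames,
                                                     n_axes), dt),
                     states = s, y_true = ytrue)
  }
  attr(out, "shutter") <- dsh
  out
}

#' Track-level realization of the binding/unbinding scenario
#'
#' Generates trajectories following the scripted states and defocus profile
#' of [binding_scenario()], with per-frame localization error s.d. derived
#' from the imaging model instead of rendering and refitting images: the
#' defocused spot width `sigma(z) = sigma0 * sqrt(1 + (z/z_R)^2)` is
#' blur-inflated by the in-frame path variance `D dt / 3`, converted to a
#' precision via the CRLB at the scenario's photon count and (decaying)
#' background, and given mild lognormal scatter (s.d. 0.15 in the log) to
#' emulate intensity fluctuations.
#'
#' @param scn A [binding_scenario()] (any scripted `sim_scenario`).
#' @param n_traj Number of trajectories.
#' @param substeps Shutter discretization substeps.
#'
#' @return As [synth_hmm_tracks()]; true states index `scn$D`.
#' @export
binding_tracks <- function(scn, n_traj = 1L, substeps = 20L) {
  stopifnot(inherits(scn, "sim_scenario"), !is.null(scn$state_script))
  n_frames <- length(scn$state_script)
  z <- rep_len(if (is.null(scn$z_script)) 0 else scn$z_script, n_frames)
  bgt <- .background_at(scn, seq_len(n_frames))
  sig_z <- scn$sigma0 * sqrt(1 + (z / scn$z_R)^2)
  eps_fun <- function(s) {
    sig_eff <- sqrt(sig_z^2 + scn$D[s] * 1e6 * scn$exposure / 3)
    base <- vapply(seq_len(n_frames), function(t)
      crlb_precision(spot_params(0, 0, N = scn$photons,
                                 b = max(bgt[t], 1e-6),
                                 sigma = sig_eff[t]), scn$cam), 0)
    base * exp(stats::rnorm(n_frames, 0, 0.15))
  }
  synth_hmm_tracks(K = length(scn$D), D = scn$D, dt = scn$frame_interval,
                   sh = shutter("continuous"), eps = eps_fun,
                   n_frames = n_frames, n_traj = n_traj,
                   substeps = substeps, state_script = scn$state_script)
}
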