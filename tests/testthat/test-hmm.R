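# Diffusive HMM: generator moments, exactness of the single-state chain,
# ELBO monotonicity, state recovery, limits and position refinement.

# dense-route exact marginal log-likelihood for one axis (flat prior on the
# first path point); independent of the package's banded recursions
dense_chain_loglik <- function(x, v, D, dt, tau, beta) {
  T <- length(x); n <- T + 1; Dn <- D * 1e6
  Vp <- 2 * Dn * dt
  W <- v + 2 * Dn * dt * beta
  J <- matrix(0, n, n); h <- numeric(n); C <- 0
  for (t in 1:T) {
    J[t, t] <- J[t, t] + 1 / Vp
    J[t + 1, t + 1] <- J[t + 1, t + 1] + 1 / Vp
    J[t, t + 1] <- J[t, t + 1] - 1 / Vp; J[t + 1, t] <- J[t, t + 1]
    c1 <- 1 - tau; c2 <- tau; r <- 1 / W[t]
    J[t, t] <- J[t, t] + r * c1^2
    J[t + 1, t + 1] <- J[t + 1, t + 1] + r * c2^2
    J[t, t + 1] <- J[t, t + 1] + r * c1 * c2; J[t + 1, t] <- J[t, t + 1]
    h[t] <- h[t] + r * x[t] * c1; h[t + 1] <- h[t + 1] + r * x[t] * c2
    C <- C + x[t]^2 * r + log(2 * pi * W[t]) + log(2 * pi * Vp)
  }
  m <- solve(J, h)
  as.numeric(-0.5 * C + 0.5 * n * log(2 * pi) -
             0.5 * determinant(J)$modulus + 0.5 * sum(h * m))
}

test_that("synthetic tracks reproduce the generative moments exactly", {
  set.seed(71)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("continuous"), eps = 30,
                         n_frames = 250000, n_traj = 1)
  bc <- blur_constants(attr(tr, "shutter"))
  d <- diff(tr[[1]]$obs$x)
  Q <- 2 * 1e6 * 0.005
  expect_equal(mean(d^2), Q * (1 - 2 * bc$R) + 2 * 900, tolerance = 0.01)
})

test_that("identity transitions never switch and seeds reproduce", {
  set.seed(72)
  tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1), A = diag(2),
                         pi0 = c(0.5, 0.5), dt = 0.005,
                         sh = shutter("continuous"), eps = 20,
                         n_frames = 200, n_traj = 3)
  for (t in tr) expect_equal(length(unique(t$states)), 1L)
  set.seed(99); a <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1,
    dt = 0.005, sh = shutter("continuous"), eps = 20, n_frames = 50)
  set.seed(99); b <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1,
    dt = 0.005, sh = shutter("continuous"), eps = 20, n_frames = 50)
  expect_identical(a[[1]]$obs$x, b[[1]]$obs$x)
})

test_that("error-free instantaneous observations collapse to the MSD
           estimator", {
  set.seed(73)
  x <- apply(matrix(rnorm(300, 0, 40), 150, 2), 2, cumsum)
  obs <- observations(x, v = matrix(0, 150, 2), dt = 0.005)
  f <- vem_fit(obs, K = 1, sh = shutter("instantaneous"))
  expect_equal(f$D * 1e6, mean(diff(x)^2) / (2 * 0.005), tolerance = 1e-6)
})

test_that("the single-state ELBO equals the exact marginal log-likelihood", {
  set.seed(74)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("continuous"), eps = 30,
                         n_frames = 200)
  obs <- tr[[1]]$obs
  f <- vem_fit(obs, K = 1)
  ll <- sum(vapply(1:2, function(a)
    dense_chain_loglik(obs$x[, a], obs$v[, a], f$D, obs$dt, f$tau,
                       f$beta), 0))
  expect_equal(f$elbo, ll, tolerance = 1e-6)
  # and mle_diffusion finds the same optimum
  md <- mle_diffusion(obs$x, obs$v, obs$dt)
  expect_equal(md$D, f$D, tolerance = 1e-3)
})

test_that("the ELBO trace is non-decreasing on every fit", {
  set.seed(75)
  A2 <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
  for (rep in 1:3) {
    tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1), A = A2, pi0 = c(.5, .5),
                           dt = 0.005, sh = shutter("continuous"),
                           eps = function(s) runif(length(s), 20, 60),
                           n_frames = 300)
    f <- vem_fit(tr[[1]]$obs, K = 2, restarts = 1, hops = 0)
    expect_true(all(diff(f$elbo_trace) > -1e-9 * abs(f$elbo)))
  }
})

test_that("two-state parameters are recovered on moderate ensembles", {
  set.seed(76)
  A2 <- matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2)
  Ds <- matrix(NA, 8, 2); Arec <- matrix(NA, 8, 2)
  for (j in 1:8) {
    tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1), A = A2, pi0 = c(.5, .5),
                           dt = 0.005, sh = shutter("continuous"),
                           eps = function(s) runif(length(s), 20, 60),
                           n_frames = 1000)
    f <- vem_fit(tr[[1]]$obs, K = 2, restarts = 2)
    Ds[j, ] <- f$D
    Arec[j, ] <- diag(f$A)
  }
  med <- apply(Ds, 2, median)
  expect_lt(abs(med[1] - 0.1) / 0.1, 0.2)
  expect_lt(abs(med[2] - 1) / 1, 0.2)
  expect_true(all(abs(apply(Arec, 2, median) - 0.97) < 0.05))
})

test_that("all variants coincide on blur-free noise-free-like data", {
  set.seed(77)
  A2 <- matrix(c(0.96, 0.04, 0.04, 0.96), 2, 2)
  tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1), A = A2, pi0 = c(.5, .5),
                         dt = 0.005, sh = shutter("instantaneous"),
                         eps = 0.5, n_frames = 1500)
  obs <- tr[[1]]$obs
  ff <- vem_fit(obs, K = 2, sh = shutter("instantaneous"), restarts = 2)
  fk <- limit_fit(obs, K = 2, variant = "kalman", restarts = 2)
  fv <- limit_fit(obs, K = 2, variant = "vbspt", restarts = 2)
  expect_equal(ff$D, fk$D, tolerance = 0.02)
  expect_equal(ff$D, fv$D, tolerance = 0.05)
})

test_that("classification behaves on one-hot and uniform posteriors", {
  g_onehot <- rbind(c(1, 0), c(0, 1), c(1, 0))
  fit <- structure(list(posterior = list(gamma = g_onehot),
                        variant = "full"), class = "diffusive_hmm")
  expect_equal(classify(fit), c(1L, 2L, 1L))
  expect_equal(misclassification(c(1, 2, 1), c(1, 2, 1)), 0)
  # uniform posterior: argmax ties resolve to state 1; against random
  # two-state truth the error rate is the truth's state-2 frequency ~ 1/2
  set.seed(78)
  truth <- sample(1:2, 2000, replace = TRUE)
  g_unif <- matrix(0.5, 2000, 2)
  fit_u <- structure(list(posterior = list(gamma = g_unif),
                          variant = "full"), class = "diffusive_hmm")
  expect_equal(misclassification(classify(fit_u), truth), 0.5,
               tolerance = 0.05)
  # relabeling by diffusion constant
  expect_equal(misclassification(c(1, 2), c(2, 1), true_D = c(1, 0.1)), 0)
})

test_that("refinement approaches the averaging limit for a static emitter", {
  set.seed(79)
  n <- 40; eps <- 25
  x <- matrix(rnorm(2 * n, 0, eps), n, 2)
  obs <- observations(x, v = matrix(eps^2, n, 2), dt = 0.005)
  m <- diffusive_hmm_model(D = 1e-12, dt = 0.005)
  ref <- refine_positions(m, obs)
  expect_equal(ref$sd1, rep(eps / sqrt(n), n), tolerance = 1e-4)
  expect_equal(ref$y1, rep(mean(x[, 1]), n), tolerance = 1e-4)
})

test_that("refinement returns the data when errors vanish", {
  # blur-free acquisition: with eps -> 0 the measurement pins the path, so
  # the refined positions coincide with the data (under continuous
  # illumination the observation keeps its motion-blur variance instead)
  set.seed(80)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("instantaneous"), eps = 0.01,
                         n_frames = 100)
  obs <- tr[[1]]$obs
  f <- vem_fit(obs, K = 1, sh = shutter("instantaneous"))
  ref <- refine_positions(f)
  expect_equal(ref$y1, obs$x[, 1], tolerance = 1e-3)
  expect_true(all(ref$sd1 < 0.1))
})

test_that("refinement reduces errors on two-state data with variable
           precision", {
  set.seed(81)
  A2 <- matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2)
  gains <- replicate(4, {
    tr <- synth_hmm_tracks(K = 2, D = c(0.1, 1), A = A2, pi0 = c(.5, .5),
                           dt = 0.005, sh = shutter("continuous"),
                           eps = function(s) runif(length(s), 20, 60),
                           n_frames = 600)
    obs <- tr[[1]]$obs; y <- tr[[1]]$y_true
    f <- vem_fit(obs, K = 2, restarts = 1)
    ref <- refine_positions(f)
    rmse_raw <- sqrt(mean((obs$x - y)^2))
    rmse_ref <- sqrt(mean((cbind(ref$y1, ref$y2) - y)^2))
    rmse_ref / rmse_raw
  })
  expect_true(mean(gains) < 1)
})

test_that("the covariance embedding holds for arbitrary valid shutters", {
  set.seed(82)
  for (i in 1:3) {
    sh <- shutter("density", values = runif(6, 0.2, 2))
    tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1,
                           dt = 0.005, sh = sh, eps = 20,
                           n_frames = 60000)
    bc <- blur_constants(attr(tr, "shutter"))
    d <- diff(tr[[1]]$obs$x)
    n <- nrow(d)
    Q <- 2 * 1e6 * 0.005
    msq <- mean(d^2)
    lag1 <- mean(d[-n, ] * d[-1, ])
    expect_equal(msq, Q * (1 - 2 * bc$R) + 2 * 400, tolerance = 0.03)
    expect_lt(abs(lag1 - (Q * bc$R - 400)), 3 * msq / sqrt(n))
  }
})

test_that("model methods expose the fit coherently", {
  set.seed(83)
  tr <- synth_hmm_tracks(K = 1, D = 0.5, A = matrix(1), pi0 = 1,
                         dt = 0.005, sh = shutter("continuous"), eps = 25,
                         n_frames = 150)
  f <- vem_fit(tr[[1]]$obs, K = 1)
  expect_output(print(f), "Diffusive HMM")
  expect_named(coef(f), c("D", "A", "pi"))
  expect_s3_class(logLik(f), "logLik")
  r <- residuals(f)
  expect_equal(dim(r), c(150, 2))
  # posterior-mean fitting shrinks standardized residuals below unit scale
  expect_gt(sd(as.numeric(r)), 0.3)
  expect_lt(sd(as.numeric(r)), 1.15)
  sim <- simulate(f, nsim = 2, seed = 1, n_frames = 50)
  expect_length(sim, 2)
  expect_equal(sim[[1]]$obs$n_frames, 50)
  p <- predict(f)
  expect_equal(nrow(p), 150)
})
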