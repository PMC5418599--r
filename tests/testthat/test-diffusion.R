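# Covariance-based and likelihood-based diffusion estimators, and the
# heuristic model corrections.

test_that("step statistics and d_cov on a deterministic ramp", {
  ss <- step_stats(c(0, 1, 2, 3))
  expect_equal(ss$msq, 1)
  expect_equal(ss$lag1, 1)
  expect_equal(as.numeric(d_cov(ss, dt = 1)), 1.5)   # 1/2 + 1
  expect_error(step_stats(c(0, 1)), "at least 3")
})

test_that("pure localization noise has the predicted step moments and zero
           d_cov", {
  set.seed(61)
  eps <- 30
  x <- rnorm(1e5, 0, eps)
  ss <- step_stats(x)
  expect_equal(ss$msq, 2 * eps^2, tolerance = 0.02)
  expect_equal(ss$lag1, -eps^2, tolerance = 0.02)
  D <- d_cov(ss, dt = 0.01)
  # moments cancel: |D| within 3 s.e. of zero
  se <- 3 * eps^2 / 0.01 / sqrt(1e5)
  expect_lt(abs(as.numeric(D)), 3 * se)
})

test_that("blurred noisy tracks reproduce the step-covariance structure", {
  set.seed(62)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("continuous"), eps = 25,
                         n_frames = 50000, n_traj = 1)
  bc <- blur_constants(attr(tr, "shutter"))
  d <- diff(tr[[1]]$obs$x)
  n <- nrow(d)
  msq <- mean(d^2)
  lag1 <- mean(d[-n, ] * d[-1, ])
  lag2 <- mean(d[-c(n - 1, n), ] * d[-(1:2), ])
  Q <- 2 * 1e6 * 0.005
  expect_equal(msq, Q * (1 - 2 * bc$R) + 2 * 625, tolerance = 0.02)
  expect_equal(lag1, Q * bc$R - 625, tolerance = 0.05)
  # lag >= 2 steps are uncorrelated within 3 s.e.
  expect_lt(abs(lag2), 3 * msq / sqrt(2 * n))
})

test_that("d_cov and d_cov_eps are unbiased across blur and noise levels", {
  set.seed(63)
  for (cfg in list(list(sh = shutter("instantaneous"), eps = 0),
                   list(sh = shutter("continuous"), eps = 30),
                   list(sh = shutter("end_pulses"), eps = 30))) {
    tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1,
                           dt = 0.005, sh = cfg$sh, eps = cfg$eps,
                           n_frames = 21, n_traj = 1500)
    bc <- blur_constants(attr(tr, "shutter"))
    Dc <- vapply(tr, function(t) as.numeric(d_cov(step_stats(t$obs$x),
                                                  0.005)), 0) / 1e6
    De <- vapply(tr, function(t)
      as.numeric(d_cov_eps(step_stats(t$obs$x), 0.005, R = bc$R,
                           mean_eps2 = cfg$eps^2)), 0) / 1e6
    expect_lt(abs(mean(Dc) - 1), 3 * sd(Dc) / sqrt(1500) + 0.01)
    expect_lt(abs(mean(De) - 1), 3 * sd(De) / sqrt(1500) + 0.01)
  }
})

test_that("d_cov_eps inverts the step-variance relation algebraically", {
  D <- 0.7; dt <- 0.01; R <- 1 / 6; eps2 <- 900
  ss <- structure(list(msq = 2 * D * dt * (1 - 2 * R) + 2 * eps2,
                       lag1 = NA, n_steps = 10, n_pairs = 9, n_axes = 1),
                  class = "step_stats")
  expect_equal(as.numeric(d_cov_eps(ss, dt, R, eps2)), D, tolerance = 1e-10)
  # R = 0, eps = 0 reduces to the MSD estimator
  ss2 <- structure(list(msq = 4, lag1 = 0, n_steps = 10, n_pairs = 9,
                        n_axes = 1), class = "step_stats")
  expect_equal(as.numeric(d_cov_eps(ss2, 1, R = 0, mean_eps2 = 0)),
               as.numeric(ss2$msq / 2))
})

test_that("mle_diffusion reduces to the MSD estimator without errors or
           blur", {
  set.seed(64)
  x <- apply(matrix(rnorm(200, 0, 50), 100, 2), 2, cumsum)
  r <- mle_diffusion(x, v = matrix(0, 100, 2), dt = 0.01,
                     sh = shutter("instantaneous"))
  expect_equal(r$D * 1e6, mean(diff(x)^2) / (2 * 0.01), tolerance = 1e-12)
  expect_equal(r$path, x)
})

test_that("mle_diffusion agrees with d_cov_eps for homogeneous errors", {
  set.seed(65)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("continuous"), eps = 30,
                         n_frames = 11, n_traj = 250)
  bc <- blur_constants(attr(tr, "shutter"))
  Dm <- vapply(tr, function(t) mle_diffusion(t$obs$x, t$obs$v, 0.005)$D, 0)
  De <- vapply(tr, function(t)
    as.numeric(d_cov_eps(step_stats(t$obs$x), 0.005, R = bc$R,
                         mean_eps2 = 900)), 0) / 1e6
  expect_lt(abs(mean(Dm) - mean(De)),
            3 * sd(Dm - De) / sqrt(250) + 0.02)
})

test_that("pointwise errors narrow the mle estimator under strongly
           heterogeneous noise", {
  set.seed(66)
  eps_mix <- function(s) sample(c(10, 80), length(s), replace = TRUE)
  tr <- synth_hmm_tracks(K = 1, D = 1, A = matrix(1), pi0 = 1, dt = 0.005,
                         sh = shutter("continuous"), eps = eps_mix,
                         n_frames = 11, n_traj = 600)
  bc <- blur_constants(attr(tr, "shutter"))
  Dm <- vapply(tr, function(t) mle_diffusion(t$obs$x, t$obs$v, 0.005)$D, 0)
  De <- vapply(tr, function(t)
    as.numeric(d_cov_eps(step_stats(t$obs$x), 0.005, R = bc$R,
                         mean_eps2 = mean(t$obs$v))), 0) / 1e6
  expect_lte(var(Dm), var(De))
})

test_that("model corrections follow the step-variance identities", {
  expect_equal(correct_D(0.8, "kalman", R = 0, mean_eps2 = 0), 0.8)
  expect_equal(correct_D(0.8, "vbspt", R = 0, mean_eps2 = 0), 0.8)
  expect_equal(correct_D(1, "kalman", R = 1 / 6), 1.5)
  # vbspt: subtract the noise floor, then undo the blur shrinkage
  expect_equal(correct_D(1, "vbspt", R = 1 / 6, mean_eps2 = 0.002,
                         dt = 0.01), (1 - 0.2) / (2 / 3))
})

test_that("negative estimates are retained and flagged", {
  ss <- structure(list(msq = 0.5, lag1 = -1, n_steps = 10, n_pairs = 9,
                       n_axes = 1), class = "step_stats")
  D <- d_cov(ss, 1)
  expect_lt(as.numeric(D), 0)
  expect_true(attr(D, "negative"))
})
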