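# Synthetic single-molecule movie generator: (multi-state) Brownian motion in
# a cell-like cylinder, motion blur by sub-frame integration, a Gaussian-beam
# defocus law, uniform (optionally decaying) background, and EMCCD noise.
# Every stage carries full ground truth.

#' Describe a simulation scenario
#'
#' The generative description of a synthetic movie: cell geometry, diffusive
#' states, frame timing, photophysics, defocus model and camera. Defaults
#' follow the canonical test conditions: diffusion at 1 um^2/s in a cylinder
#' of length 20 um and diameter 0.8 um (a long E. coli-like cell, avoiding
#' longitudinal confinement artifacts), 80 nm pixels, EM gain 50, readout
#' s.d. 10.
#'
#' @param D Per-state diffusion constants, um^2/s.
#' @param rates Transition rate matrix (1/s) between states (CTMC), or `NULL`
#'   for a single state / scripted states.
#' @param state_script Optional integer vector of per-frame states (overrides
#'   `rates`).
#' @param z_script Optional numeric vector of per-frame z coordinates (nm);
#'   when given, z does not diffuse.
#' @param cyl_length,cyl_diameter Cylinder geometry, um. The cylinder axis is
#'   x; y and z are transverse.
#' @param frame_interval Frame interval (s).
#' @param exposure Exposure time (s); defaults to the full frame interval
#'   (continuous illumination).
#' @param substeps Brownian substeps per frame interval (>= 10).
#' @param photons Mean photons per spot per frame.
#' @param background Background photons/pixel: a single value, or
#'   `c(start, end)` with exponential decay controlled by `bg_time_constant`.
#' @param bg_time_constant Background decay time constant (s).
#' @param wavelength,na Emission wavelength (nm) and numerical aperture.
#' @param z_R Defocus depth scale (nm): the spot width grows as
#'   `sigma0 * sqrt(1 + (z/z_R)^2)`.
#' @param cam A [camera_model()].
#' @param fov Rendered frame size in pixels (square).
#'
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(D = 1, rates = NULL, state_script = NULL,
                         z_script = NULL,
                         cyl_length = 20, cyl_diameter = 0.8,
                         frame_interval = 0.005, exposure = NULL,
                         substeps = 20L, photons = 300,
                         background = 1, bg_time_constant = Inf,
                         wavelength = 639, na = 1.4, z_R = 400,
                         cam = camera_model(), fov = 15L) {
  if (is.null(exposure)) exposure <- frame_interval
  stopifnot(all(D >= 0), frame_interval > 0, exposure > 0,
            exposure <= frame_interval + 1e-12, substeps >= 10,
            photons >= 0, all(background >= 0), bg_time_constant > 0,
            inherits(cam, "camera_model"))
  if (!is.null(rates)) {
    rates <- as.matrix(rates)
    stopifnot(nrow(rates) == length(D), ncol(rates) == length(D),
              all(rates[row(rates) != col(rates)] >= 0))
  }
  structure(list(D = D, rates = rates, state_script = state_script,
                 z_script = z_script,
                 cyl_length = cyl_length, cyl_diameter = cyl_diameter,
                 frame_interval = frame_interval, exposure = exposure,
                 substeps = as.integer(substeps), photons = photons,
                 background = background, bg_time_constant = bg_time_constant,
                 wavelength = wavelength, na = na, z_R = z_R,
                 sigma0 = sigma0(wavelength, na), cam = cam,
                 fov = as.integer(fov)),
            class = "sim_scenario")
}

# specular reflection of transverse coordinates into the cylinder, and of the
# axial coordinate at the end caps; applied per substep
.reflect_cylinder <- function(x, y, z, half_len, radius) {
  # axial caps: fold into [-half_len, half_len]
  x <- abs(x + half_len) %% (4 * half_len)
  x <- ifelse(x > 2 * half_len, 4 * half_len - x, x) - half_len
  r <- sqrt(y^2 + z^2)
  out <- r > radius
  if (any(out)) {
    rr <- r[out]
    # fold the radius; one reflection suffices for substep-scale excursions
    rnew <- pmin(2 * radius - rr, radius * (2 - 1e-9))
    rnew <- pmax(rnew, 0)
    y[out] <- y[out] * rnew / rr
    z[out] <- z[out] * rnew / rr
  }
  list(x = x, y = y, z = z)
}

#' Simulate a ground-truth path through a scenario
#'
#' Euler-Maruyama Brownian substeps (`x <- x + sqrt(2 D_s dt_sub) * xi` per
#' axis) with specular reflection at the cylinder wall and end caps; the
#' diffusive state switches as a discrete-time Markov chain per frame
#' (from `rates`, matrix-exponential-free first-order discretization) or
#' follows `state_script`. Reproducible under `set.seed()`.
#'
#' @param scn A [sim_scenario()].
#' @param n_frames Number of frames.
#' @param origin Optional starting position `c(x, y, z)` in nm; default
#'   cylinder centre.
#'
#' @return A list of class `ground_truth`: `path` (substep positions, nm,
#'   `(n_frames * substeps + 1) x 3`), `frame_pos` (exposure-averaged
#'   positions per frame, nm), `states` (per frame), `z` (per-frame mean z,
#'   nm), `n_frames`, and the scenario.
#' @export
simulate_path <- function(scn, n_frames, origin = NULL) {
  stopifnot(inherits(scn, "sim_scenario"), n_frames >= 1)
  m <- scn$substeps
  dt_sub <- scn$frame_interval / m
  half_len <- scn$cyl_length / 2 * 1e3   # nm
  radius <- scn$cyl_diameter / 2 * 1e3   # nm

  # per-frame states
  K <- length(scn$D)
  if (!is.null(scn$state_script)) {
    states <- rep_len(scn$state_script, n_frames)
  } else if (K == 1L || is.null(scn$rates)) {
    states <- rep(1L, n_frames)
  } else {
    P <- diag(K) + scn$rates * scn$frame_interval
    P[P < 0] <- 0
    P <- P / rowSums(P)
    states <- integer(n_frames)
    states[1] <- sample.int(K, 1)
    for (t in seq_len(n_frames - 1))
      states[t + 1] <- sample.int(K, 1, prob = P[states[t], ])
  }

  if (is.null(origin)) origin <- c(0, 0, 0)
  n_sub <- n_frames * m
  pos <- matrix(NA_real_, n_sub + 1, 3)
  pos[1, ] <- origin
  sub_state <- rep(states, each = m)
  sd_sub <- sqrt(2 * scn$D[sub_state] * 1e6 * dt_sub)  # nm
  noise <- matrix(stats::rnorm(3 * n_sub), n_sub, 3) * sd_sub
  scripted_z <- !is.null(scn$z_script)
  zs <- if (scripted_z) rep(rep_len(scn$z_script, n_frames), each = m)
  for (i in seq_len(n_sub)) {
    p <- pos[i, ] + noise[i, ]
    r <- .reflect_cylinder(p[1], p[2], p[3], half_len, radius)
    pos[i + 1, ] <- c(r$x, r$y, r$z)
    if (scripted_z) pos[i + 1, 3] <- zs[i]
  }
  if (scripted_z) pos[1, 3] <- zs[1]

  # exposure-averaged position per frame over the exposed substeps
  expo_frac <- scn$exposure / scn$frame_interval
  m_exp <- max(1L, round(expo_frac * m))
  frame_pos <- matrix(NA_real_, n_frames, 3)
  for (t in seq_len(n_frames)) {
    idx <- (t - 1) * m + seq_len(m_exp)
    # average of substep midpoints approximated by endpoint means
    frame_pos[t, ] <- colMeans((pos[idx, , drop = FALSE] +
                                pos[idx + 1, , drop = FALSE]) / 2)
  }
  structure(list(path = pos, frame_pos = frame_pos, states = states,
                 z = frame_pos[, 3], n_frames = n_frames, scenario = scn),
            class = "ground_truth")
}

#' Motion-blur strength of an exposure
#'
#' Ratio of the in-plane s.d. of the diffusion path during the exposure
#' around its exposure-averaged position, `sqrt(D * t_E / 3)` per axis, to
#' the diffraction-limited spot width. Ratios below 0.5 are weak blur.
#'
#' @param D Diffusion constant, um^2/s.
#' @param t_E Exposure time, s.
#' @param wavelength Wavelength, nm.
#' @param na Numerical aperture.
#'
#' @return Dimensionless blur ratio.
#' @examples
#' blur_ratio(1, 0.006, 639, 1.4)  # ~ 0.47: the weak-blur boundary
#' @export
blur_ratio <- function(D, t_E, wavelength = 639, na = 1.4) {
  stopifnot(all(D >= 0), all(t_E >= 0))
  1e3 * sqrt(D * t_E / 3) / sigma0(wavelength, na)
}

# background level at frame t (1-based), photons/pixel
.background_at <- function(scn, t) {
  bg <- scn$background
  if (length(bg) == 1L || !is.finite(scn$bg_time_constant)) return(bg[1])
  tt <- (t - 1) * scn$frame_interval
  bg[2] + (bg[1] - bg[2]) * exp(-tt / scn$bg_time_constant)
}

#' Render a movie from a ground-truth path
#'
#' For each frame, the expected photon map is accumulated over the exposed
#' substeps: each substep deposits `photons/substeps` expected photons
#' through a pixel-integrated Gaussian profile of width
#' `sigma0 * sqrt(1 + (z/z_R)^2)` centred at the instantaneous position
#' (motion blur and defocus broadening), on top of the per-frame background;
#' EMCCD counts are then drawn with [sample_counts()]. The rendered window
#' follows the spot: each frame's field of view is centred on the pixel
#' containing the exposure-averaged position.
#'
#' @param scn A [sim_scenario()].
#' @param truth A [simulate_path()] result generated from `scn`.
#'
#' @return List of class `sim_movie`: `stack` (array `fov x fov x n_frames`,
#'   camera counts), `seeds` (data.frame per frame: `frame`, window origin
#'   `origin_x_px`, `origin_y_px`, seed position `x_px`, `y_px` in window
#'   coordinates, and the true averaged position in nm), `truth`, `scenario`.
#' @export
render_movie <- function(scn, truth) {
  stopifnot(inherits(scn, "sim_scenario"), inherits(truth, "ground_truth"))
  if (!identical(truth$scenario$substeps, scn$substeps) ||
      truth$n_frames < 1)
    stop("render_movie: truth does not match the scenario")
  n_frames <- truth$n_frames
  m <- scn$substeps
  a <- scn$cam$pixel_size
  fov <- scn$fov
  expo_frac <- scn$exposure / scn$frame_interval
  m_exp <- max(1L, round(expo_frac * m))
  stack <- array(NA_real_, c(fov, fov, n_frames))
  seeds <- data.frame(frame = seq_len(n_frames), origin_x_px = NA_real_,
                      origin_y_px = NA_real_, x_px = NA_real_,
                      y_px = NA_real_, true_x_nm = truth$frame_pos[, 1],
                      true_y_nm = truth$frame_pos[, 2],
                      true_z_nm = truth$frame_pos[, 3])
  g <- roi_geometry(c(0, 0), fov, fov, pixel_size = a)
  for (t in seq_len(n_frames)) {
    ctr <- truth$frame_pos[t, 1:2]
    org <- floor(ctr / a) - floor(fov / 2)  # window origin, pixels
    E <- matrix(.background_at(scn, t), fov, fov)
    idx <- (t - 1) * m + seq_len(m_exp)
    for (i in idx) {
      p_sub <- (truth$path[i, ] + truth$path[i + 1, ]) / 2
      sig <- scn$sigma0 * sqrt(1 + (p_sub[3] / scn$z_R)^2)
      sp <- spot_params(p_sub[1] - org[1] * a, p_sub[2] - org[2] * a,
                        N = scn$photons / m_exp, b = 1e-12, sigma = sig)
      E <- E + (pixel_intensities(sp, g) - 1e-12)
    }
    stack[, , t] <- sample_counts(E, scn$cam)
    seeds$origin_x_px[t] <- org[1]
    seeds$origin_y_px[t] <- org[2]
    seeds$x_px[t] <- ctr[1] / a - org[1]
    seeds$y_px[t] <- ctr[2] / a - org[2]
  }
  structure(list(stack = stack, seeds = seeds, truth = truth,
                 scenario = scn), class = "sim_movie")
}

#' Extract a square ROI around a seed position
#'
#' @param frame Count matrix (one movie frame).
#' @param seed `c(x_px, y_px)` seed position in frame pixel coordinates.
#' @param size ROI side length in pixels.
#'
#' @return List: `roi` (size x size count matrix), `origin` (pixel indices of
#'   the ROI corner in the frame), `seed_in_roi` (seed in ROI coordinates).
#' @export
extract_roi <- function(frame, seed, size = 9L) {
  stopifnot(is.matrix(frame), length(seed) == 2)
  org <- round(seed) - size %/% 2
  org <- pmax(org, 0)
  org <- pmin(org, c(ncol(frame), nrow(frame)) - size)
  roi <- frame[org[2] + seq_len(size), org[1] + seq_len(size), drop = FALSE]
  list(roi = roi, origin = org, seed_in_roi = seed - org)
}

#' Two-state binding/unbinding scenario with defocused events
#'
#' A scripted two-state scenario for event-detection benchmarks: a molecule
#' alternating between free diffusion (D = 1 um^2/s) and a bound state
#' emulated by slow diffusion (D = 0.1 um^2/s), with four binding events of
#' different durations, two of which occur about 400 nm out of focus
#' (roughly the radius of an E. coli cell, as for membrane binding). Imaging
#' at 200 Hz (5 ms frames) under continuous illumination with 300 photons
#' per spot and a background decaying exponentially from 0.95 to 0.75
#' photons/pixel with a 0.75 s time constant.
#'
#' @param defocus_scale Multiplies all scripted z coordinates (e.g. 0.2
#'   rescales z by 1/5, removing most defocus effects).
#' @param n_frames Scenario length in frames.
#'
#' @return A [sim_scenario()] with `state_script` and `z_script` set; the
#'   event table is attached as attribute `"events"`.
#' @export
binding_scenario <- function(defocus_scale = 1, n_frames = 600L) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 500L)
  # four bound intervals (state 2), two at z ~ 400 nm
  ev <- data.frame(
    start = as.integer(round(n_frames * c(0.13, 0.33, 0.53, 0.73))),
    end   = as.integer(round(n_frames * c(0.23, 0.38, 0.63, 0.78))),
    z_nm  = c(400, 0, 400, 0))
  states <- rep(1L, n_frames)
  zsc <- rep(0, n_frames)
  for (i in seq_len(nrow(ev))) {
    idx <- ev$start[i]:ev$end[i]
    states[idx] <- 2L
    zsc[idx] <- ev$z_nm[i]
  }
  scn <- sim_scenario(D = c(1, 0.1), state_script = states,
                      z_script = zsc * defocus_scale,
                      frame_interval = 0.005, photons = 300,
                      background = c(0.95, 0.75), bg_time_constant = 0.75)
  attr(scn, "events") <- ev
  scn
}
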