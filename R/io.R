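# File formats: multi-page TIFF stacks, localization / trajectory CSV
# tables, YAML camera and scenario configuration. Lengths are nm and times
# seconds in all files; pixel units exist only inside the localizer.

#' Read a multi-page TIFF stack
#'
#' @param path Path to a multi-page TIFF (16-bit unsigned or float).
#'
#' @return Numeric array `height x width x n_frames` in acquisition order;
#'   16-bit files are returned as raw counts.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("read_stack: unreadable TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("read_stack: pages of '", path, "' differ in size (page ",
         which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1], ")")
  array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
}

#' Write a count stack as a 16-bit multi-page TIFF
#'
#' Counts are rounded and clipped to `[0, 65535]`; integer-valued counts in
#' range round-trip exactly through [read_stack()].
#'
#' @param stack Array `height x width x n_frames` (or a matrix).
#' @param path Output path.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  frames <- lapply(seq_len(dim(stack)[3]), function(t)
    pmin(pmax(round(stack[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

.locs_required <- c("frame", "x_nm", "y_nm")

#' Write a localization table
#'
#' Fixed schema, one row per fit: `frame`, `x_nm`, `y_nm`, `sd_x_nm`,
#' `sd_y_nm`, `N`, `b`, `sigma_nm` (or `sigma1_nm`, `sigma2_nm`, `phi` for
#' asymmetric fits), `crlb_nm`, `converged`, `retained`, plus any
#' per-criterion flag columns present. Extra columns are preserved.
#'
#' @param df data.frame with at least `frame`, `x_nm`, `y_nm`.
#' @param path Output CSV path.
#' @export
write_locs <- function(df, path) {
  miss <- setdiff(.locs_required, names(df))
  if (length(miss))
    stop("write_locs: missing required column(s): ",
         paste(miss, collapse = ", "))
  canon <- c(.locs_required, "sd_x_nm", "sd_y_nm", "N", "b", "sigma_nm",
             "sigma1_nm", "sigma2_nm", "phi", "crlb_nm", "converged",
             "retained")
  ord <- c(intersect(canon, names(df)), setdiff(names(df), canon))
  utils::write.csv(df[ord], path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table
#'
#' @param path CSV path.
#' @return data.frame; errors name any missing required column.
#' @export
read_locs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.locs_required, names(df))
  if (length(miss))
    stop("read_locs: missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Collect fits into a localization table
#'
#' @param fits List of `spot_fit` objects.
#' @param frames Frame indices (default sequential).
#' @param flags Optional [filter_fits()] result to merge.
#' @return data.frame in the [write_locs()] schema.
#' @export
locs_table <- function(fits, frames = seq_along(fits), flags = NULL) {
  stopifnot(length(frames) == length(fits))
  sym <- fits[[1]]$model == "symmetric"
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    base <- data.frame(frame = frames[i], x_nm = f$params$mu_x,
                       y_nm = f$params$mu_y, sd_x_nm = f$precision_x,
                       sd_y_nm = f$precision_y, N = f$params$N,
                       b = f$params$b)
    if (sym) {
      base$sigma_nm <- f$params$sigma
    } else {
      base$sigma1_nm <- f$params$sigma1
      base$sigma2_nm <- f$params$sigma2
      base$phi <- f$params$phi
    }
    base$crlb_nm <- f$crlb_sd
    base$converged <- f$converged
    base
  })
  df <- do.call(rbind, rows)
  if (!is.null(flags)) {
    df$retained <- flags$retained
    df$dist_ok <- flags$dist_ok
    df$sd_ok <- flags$sd_ok
    df$width_ok <- flags$width_ok
  }
  df
}

#' Split a trajectory table into observation objects
#'
#' Expects columns `traj_id`, `frame`, `x_nm`, `y_nm` and optionally
#' `sd_x_nm`, `sd_y_nm`. Without the precision columns, the observations
#' carry `v = NULL` and estimators requiring pointwise precision refuse with
#' a clear error.
#'
#' @param df data.frame (e.g. from [read_locs()] with a `traj_id` column).
#' @param dt Frame interval, s.
#' @return Named list of [observations()] objects, one per trajectory.
#' @export
traj_to_obs <- function(df, dt) {
  need <- c("traj_id", "frame", "x_nm", "y_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("traj_to_obs: missing required column(s): ",
         paste(miss, collapse = ", "))
  has_sd <- all(c("sd_x_nm", "sd_y_nm") %in% names(df))
  lapply(split(df, df$traj_id), function(g) {
    g <- g[order(g$frame), ]
    x <- cbind(g$x_nm, g$y_nm)
    v <- if (has_sd) cbind(g$sd_x_nm^2, g$sd_y_nm^2) else NULL
    observations(x, v, dt)
  })
}

#' Read a camera calibration block from YAML
#'
#' Expects keys `gain`, `offset`, `readout_sd`, `pixel_size_nm` (top level
#' or under `camera:`).
#'
#' @param path YAML file path.
#' @return A [camera_model()].
#' @export
read_camera <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$camera)) y <- y$camera
  need <- c("gain", "offset", "readout_sd", "pixel_size_nm")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("read_camera: missing key(s): ", paste(miss, collapse = ", "))
  camera_model(gain = y$gain, offset = y$offset, readout_sd = y$readout_sd,
               pixel_size = y$pixel_size_nm)
}

#' Read a simulation scenario from YAML
#'
#' Expects a top-level `camera` block (see [read_camera()]) and a `scenario`
#' block whose keys map onto [sim_scenario()] arguments: `D` (scalar or
#' list, um^2/s), `frame_interval_s`, `exposure_s`, `substeps`, `photons`,
#' `background` (scalar or `[start, end]`), `bg_time_constant_s`,
#' `cyl_length_um`, `cyl_diameter_um`, `wavelength_nm`, `na`, `z_R_nm`,
#' `fov_px`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [sim_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  cam <- if (!is.null(y$camera)) read_camera(path) else camera_model()
  sc <- y$scenario
  if (is.null(sc)) stop("read_scenario: missing 'scenario' block")
  known <- c("D", "frame_interval_s", "exposure_s", "substeps", "photons",
             "background", "bg_time_constant_s", "cyl_length_um",
             "cyl_diameter_um", "wavelength_nm", "na", "z_R_nm", "fov_px")
  bad <- setdiff(names(sc), known)
  if (length(bad))
    stop("read_scenario: unknown scenario key(s): ",
         paste(bad, collapse = ", "))
  arg <- list(cam = cam)
  pick <- function(key, to) if (!is.null(sc[[key]])) arg[[to]] <<-
    unlist(sc[[key]])
  pick("D", "D"); pick("frame_interval_s", "frame_interval")
  pick("exposure_s", "exposure"); pick("substeps", "substeps")
  pick("photons", "photons"); pick("background", "background")
  pick("bg_time_constant_s", "bg_time_constant")
  pick("cyl_length_um", "cyl_length"); pick("cyl_diameter_um",
                                            "cyl_diameter")
  pick("wavelength_nm", "wavelength"); pick("na", "na")
  pick("z_R_nm", "z_R"); pick("fov_px", "fov")
  do.call(sim_scenario, arg)
}

#' Write a fitted diffusive HMM as JSON
#'
#' @param fit A `diffusive_hmm`.
#' @param path Output path.
#' @export
write_hmm <- function(fit, path) {
  stopifnot(inherits(fit, "diffusive_hmm"))
  jsonlite::write_json(
    list(K = fit$K, D_um2_s = fit$D, A = fit$A, pi = fit$pi, R = fit$R,
         tau = fit$tau, beta = fit$beta, dt_s = fit$dt, elbo = fit$elbo,
         variant = fit$variant),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
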