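#' Maximum-intensity z-projection of one frame
#'
#' @param stack an [image_stack()].
#' @param frame frame index (1-based).
#' @return A 2D matrix (y, x) with the same xy calibration as the stack.
#' @export
project_frame <- function(stack, frame) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (frame < 1 || frame > d[1]) stop("frame out of range")
  apply(stack$data[frame, , , , drop = TRUE], c(2, 3), max)
}

# odd window side (px) closest to a physical side length; ties toward smaller
.odd_window_px <- function(side_um, pixel_size) {
  target <- side_um / pixel_size
  lo <- max(1L, as.integer(2 * floor((target - 1) / 2) + 1)) # largest odd <= target
  hi <- lo + 2L
  if (abs(lo - target) <= abs(hi - target)) lo else hi
}

#' Select the best z-slice for an xy position
#'
#' Returns the z-slice with the maximum mean intensity of the 500 x 500 nm
#' xy-region surrounding the given position (window converted to whole
#' pixels, nearest odd side, minimum 1 x 1; clipped at image borders).
#' Ties break toward the lower z index.
#'
#' @param stack an [image_stack()].
#' @param frame frame index.
#' @param xy_um c(x, y) position in um.
#' @param window_nm side of the square window (nm).
#' @return The selected z index (1-based).
#' @export
select_z <- function(stack, frame, xy_um, window_nm = 500) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  px <- stack$pixel_size_xy
  ix <- max(1L, min(d[4], ceiling(xy_um[1] / px)))
  iy <- max(1L, min(d[3], ceiling(xy_um[2] / px)))
  half <- (.odd_window_px(window_nm / 1000, px) - 1L) %/% 2L
  xs <- max(1L, ix - half):min(d[4], ix + half)
  ys <- max(1L, iy - half):min(d[3], iy + half)
  means <- vapply(seq_len(d[2]),
                  function(z) mean(stack$data[frame, z, ys, xs]), numeric(1))
  which.max(means) # first max = lowest z on ties
}

#' Seed approximate 3D centres at an anchor frame
#'
#' In `provided` mode, replays click coordinates (the manual workflow); in
#' `auto` mode, finds local maxima of the max-intensity projection above a
#' robust threshold (median + `k_mad` * MAD), enforcing a minimum mutual
#' distance. Each xy seed is assigned a z-slice by [select_z()].
#'
#' @param stack an [image_stack()].
#' @param frame frame index.
#' @param mode `"auto"` or `"provided"`.
#' @param seeds for `provided` mode: matrix or data.frame with columns
#'   x_um, y_um.
#' @param k_mad robust threshold multiplier (auto mode).
#' @param min_distance_um minimum mutual distance between auto seeds (um).
#' @return A matrix with columns x_um, y_um, z_um (0 rows if nothing found;
#'   auto mode warns rather than errors).
#' @export
seed_anchor <- function(stack, frame, mode = c("auto", "provided"),
                        seeds = NULL, k_mad = 3, min_distance_um = 1) {
  mode <- match.arg(mode)
  px <- stack$pixel_size_xy
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  if (mode == "provided") {
    if (is.null(seeds)) stop("mode = 'provided' requires seeds")
    seeds <- as.matrix(as.data.frame(seeds)[, c("x_um", "y_um")])
    xy <- seeds
  } else {
    proj <- project_frame(stack, frame)
    thr <- stats::median(proj) + k_mad * stats::mad(proj)
    ny <- nrow(proj); nx <- ncol(proj)
    cand <- which(proj > thr, arr.ind = TRUE)
    if (nrow(cand)) {
      is_max <- vapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; c <- cand[i, 2]
        nb <- proj[max(1, r - 1):min(ny, r + 1), max(1, c - 1):min(nx, c + 1)]
        proj[r, c] >= max(nb)
      }, logical(1))
      cand <- cand[is_max, , drop = FALSE]
    }
    if (!nrow(cand)) {
      warning("no local maxima found above threshold")
      return(empty)
    }
    vals <- proj[cand]
    ord <- order(-vals, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      p <- c(cand[i, 2] - 0.5, cand[i, 1] - 0.5) * px
      ok <- TRUE
      for (j in keep) {
        q <- c(cand[j, 2] - 0.5, cand[j, 1] - 0.5) * px
        if (sqrt(sum((p - q)^2)) < min_distance_um) { ok <- FALSE; break }
      }
      if (ok) keep <- c(keep, i)
    }
    cand <- cand[keep, , drop = FALSE]
    xy <- cbind((cand[, 2] - 0.5) * px, (cand[, 1] - 0.5) * px)
  }
  if (!nrow(xy)) return(empty)
  out <- t(vapply(seq_len(nrow(xy)), function(i) {
    z <- select_z(stack, frame, xy[i, ])
    c(xy[i, 1], xy[i, 2], (z - 0.5) * stack$z_spacing)
  }, numeric(3)))
  colnames(out) <- c("x_um", "y_um", "z_um")
  out
}

#' Find the brightest voxel within a spherical mask
#'
#' Searches the sphere of the given physical radius (anisotropic voxels
#' honoured) about a predicted centre and returns the centre of the voxel
#' of maximal intensity, or `NULL` if no voxel exceeds the background
#' threshold (median + 3 MAD of the frame by default). Equal-intensity
#' maxima break ties toward the voxel nearest the prediction, then lowest
#' z, y, x.
#'
#' @param stack an [image_stack()].
#' @param frame frame index.
#' @param predicted_center c(x, y, z) in um.
#' @param radius sphere radius (um).
#' @param threshold background threshold; `NULL` for median + 3 MAD.
#' @return c(x_um, y_um, z_um) of the selected voxel centre, or `NULL`.
#' @export
detect_in_mask <- function(stack, frame, predicted_center, radius,
                           threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  .check_positive(radius, "radius")
  d <- dim(stack$data)
  px <- stack$pixel_size_xy; zs <- stack$z_spacing
  p <- as.numeric(predicted_center)
  xs <- max(1L, floor((p[1] - radius) / px)):min(d[4], ceiling((p[1] + radius) / px) + 1L)
  ys <- max(1L, floor((p[2] - radius) / px)):min(d[3], ceiling((p[2] + radius) / px) + 1L)
  zsl <- max(1L, floor((p[3] - radius) / zs)):min(d[2], ceiling((p[3] + radius) / zs) + 1L)
  xs <- xs[xs >= 1 & xs <= d[4]]; ys <- ys[ys >= 1 & ys <= d[3]]
  zsl <- zsl[zsl >= 1 & zsl <= d[2]]
  grid <- expand.grid(z = zsl, y = ys, x = xs)
  cx <- (grid$x - 0.5) * px; cy <- (grid$y - 0.5) * px; cz <- (grid$z - 0.5) * zs
  dist <- sqrt((cx - p[1])^2 + (cy - p[2])^2 + (cz - p[3])^2)
  inside <- dist <= radius
  if (!any(inside)) {
    warning("spherical mask contains no voxels inside the volume")
    return(NULL)
  }
  grid <- grid[inside, , drop = FALSE]
  dist <- dist[inside]
  vals <- stack$data[frame, , , ][cbind(grid$z, grid$y, grid$x)]
  if (is.null(threshold)) {
    fr <- stack$data[frame, , , ]
    threshold <- stats::median(fr) + 3 * stats::mad(fr)
  }
  vmax <- max(vals)
  if (vmax <= threshold) return(NULL)
  cand <- which(vals == vmax)
  cand <- cand[order(dist[cand], grid$z[cand], grid$y[cand], grid$x[cand])]
  i <- cand[1]
  c(x_um = (grid$x[i] - 0.5) * px, y_um = (grid$y[i] - 0.5) * px,
    z_um = (grid$z[i] - 0.5) * zs)
}

#' Subpixel 3D Gaussian refinement of a spot centre
#'
#' Fits an axis-aligned anisotropic 3D Gaussian plus constant offset to a
#' local window (default 7 x 7 x 5 voxels) by nonlinear least squares.
#' On fit failure or a degenerate (flat) window, falls back to the
#' intensity-weighted centroid, flagged in `method`.
#'
#' @param stack an [image_stack()].
#' @param frame frame index.
#' @param approx_center c(x, y, z) in um.
#' @param window_xy,window_z window size in voxels (odd).
#' @param source provenance label stored with the observation
#'   (`"anchor-seed"` or `"propagated"`).
#' @return A list of class `spot_observation`: `frame`, `center` (um),
#'   `amplitude`, `sigma` (um, c(xy, xy, z)), `fit_residual` (RMS residual
#'   / amplitude), `method` (`"gaussian"` or `"centroid"`), `source`.
#' @export
fit_gaussian_3d <- function(stack, frame, approx_center,
                            window_xy = 7, window_z = 5,
                            source = "propagated") {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  px <- stack$pixel_size_xy; zs <- stack$z_spacing
  p <- as.numeric(approx_center)
  ix <- max(1L, min(d[4], ceiling(p[1] / px)))
  iy <- max(1L, min(d[3], ceiling(p[2] / px)))
  iz <- max(1L, min(d[2], ceiling(p[3] / zs)))
  hx <- (window_xy - 1) %/% 2; hz <- (window_z - 1) %/% 2
  xs <- max(1L, ix - hx):min(d[4], ix + hx)
  ys <- max(1L, iy - hx):min(d[3], iy + hx)
  zsl <- max(1L, iz - hz):min(d[2], iz + hz)
  grid <- expand.grid(z = (zsl - 0.5) * zs, y = (ys - 0.5) * px,
                      x = (xs - 0.5) * px)
  vals <- as.vector(stack$data[frame, zsl, ys, xs])
  off0 <- min(vals); amp0 <- max(vals) - off0

  centroid_obs <- function() {
    w <- pmax(vals - off0, 0)
    ctr <- if (sum(w) > 0) {
      c(sum(w * grid$x), sum(w * grid$y), sum(w * grid$z)) / sum(w)
    } else {
      c(mean(grid$x), mean(grid$y), mean(grid$z))
    }
    structure(list(frame = frame, center = ctr, amplitude = max(amp0, 0),
                   sigma = c(NA_real_, NA_real_, NA_real_),
                   fit_residual = NA_real_, method = "centroid",
                   source = source), class = "spot_observation")
  }
  if (amp0 <= 0) return(centroid_obs())

  w <- pmax(vals - off0, 0)
  start <- list(x0 = sum(w * grid$x) / sum(w), y0 = sum(w * grid$y) / sum(w),
                z0 = sum(w * grid$z) / sum(w), sxy = 2 * px, sz = 1.5 * zs,
                A = amp0, off = off0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vals ~ off + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sxy^2) -
                             (z - z0)^2 / (2 * sz^2)),
      data = data.frame(vals = vals, x = grid$x, y = grid$y, z = grid$z),
      start = start,
      lower = c(x0 = min(grid$x), y0 = min(grid$y), z0 = min(grid$z),
                sxy = px / 10, sz = zs / 10, A = 0, off = -Inf),
      upper = c(x0 = max(grid$x), y0 = max(grid$y), z0 = max(grid$z),
                sxy = 10 * px, sz = 10 * zs, A = Inf, off = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(centroid_obs())
  cf <- stats::coef(fit)
  if (cf[["A"]] <= 0) return(centroid_obs())
  rms <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(
    frame = frame,
    center = c(cf[["x0"]], cf[["y0"]], cf[["z0"]]),
    amplitude = cf[["A"]],
    sigma = c(cf[["sxy"]], cf[["sxy"]], cf[["sz"]]),
    fit_residual = rms / cf[["A"]],
    method = "gaussian",
    source = source
  ), class = "spot_observation")
}
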