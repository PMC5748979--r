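#' Calibrated 4D image stack
#'
#' Container for a (t, z, y, x) intensity array with voxel calibration.
#' Coordinates are physical um with the origin at the corner of voxel
#' (1,1,1); voxel centres sit at `(i - 0.5) * spacing` for 1-based `i`.
#'
#' @param data 4D numeric array, dimensions (t, z, y, x), non-negative.
#' @param pixel_size_xy xy pixel size (um).
#' @param z_spacing z spacing (um).
#' @param frame_interval frame interval (s).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_xy, z_spacing, frame_interval) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  .check_positive(pixel_size_xy, "pixel_size_xy")
  .check_positive(z_spacing, "z_spacing")
  .check_positive(frame_interval, "frame_interval")
  if (any(data < 0)) stop("image data must be non-negative")
  structure(list(data = data, pixel_size_xy = pixel_size_xy,
                 z_spacing = z_spacing, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d frames, %d z-slices, %d x %d px (xy %.3g um, z %.3g um, dt %.3g s)\n",
    d[1], d[2], d[3], d[4], x$pixel_size_xy, x$z_spacing, x$frame_interval))
  invisible(x)
}

#' Write an image stack as multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are ordered t-major, then z (TZYX). Intensities are stored as
#' 32-bit samples scaled to \[0, 1\]; the scale and all calibration live in
#' `<path>.json`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- matrix(stack$data[t, z, , ] / scale, d[3], d[4])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(n_frames = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
               pixel_size_xy_um = stack$pixel_size_xy,
               z_spacing_um = stack$z_spacing,
               frame_interval_s = stack$frame_interval,
               intensity_scale = scale, page_order = "TZYX")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; calibration is read from `<path>.json` unless
#'   supplied explicitly.
#' @param pixel_size_xy,z_spacing,frame_interval explicit calibration
#'   overrides (um, um, s).
#' @return An `image_stack`.
#' @export
read_stack <- function(path, pixel_size_xy = NULL, z_spacing = NULL,
                       frame_interval = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  pixel_size_xy <- pixel_size_xy %||% meta$pixel_size_xy_um
  z_spacing <- z_spacing %||% meta$z_spacing_um
  frame_interval <- frame_interval %||% meta$frame_interval_s
  if (is.null(pixel_size_xy) || is.null(z_spacing) || is.null(frame_interval))
    stop("missing calibration metadata: supply pixel_size_xy, z_spacing and frame_interval explicitly")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$intensity_scale %||% 1
  n_z <- meta$n_z %||% length(pages)
  n_t <- length(pages) / n_z
  if (n_t != round(n_t)) stop("page count is not a multiple of n_z")
  d1 <- dim(pages[[1]])
  data <- array(0, dim = c(n_t, n_z, d1[1], d1[2]))
  i <- 0L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    i <- i + 1L
    data[t, z, , ] <- pages[[i]] * scale
  }
  image_stack(data, pixel_size_xy, z_spacing, frame_interval)
}
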