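#' Motion parameters for a simulated centrosome pair
#'
#' Defines the biphasic separation dynamics of one centrosome pair: a
#' confined, mean-reverting "search-and-capture" phase, followed (for pairs
#' flagged `cluster = TRUE`) by a "motorized" phase in which separation
#' decreases linearly to a clustered plateau once the pair first comes
#' within `onset_separation`.
#'
#' Defaults encode the empirical magnitudes of the biphasic clustering
#' model: the motorized phase starts at 7-8 um separation (default onset
#' 7.5 um) and lasts 15 min (900 s); non-clustering pairs fluctuate about
#' 11.5 um; the search-phase temporal SD is ~2 um in wild-type-like cells
#' (1 um in contractile knockout-like cells); frames are 40 s apart.
#' Pairs destined to cluster search at a lower baseline (8.5 um) so that
#' the onset distance lies within reach of the confined fluctuation.
#'
#' @param cluster logical; does this pair complete clustering?
#' @param mean_separation_search baseline separation (um) during the
#'   search-and-capture phase. Default depends on `cluster`.
#' @param sd_search stationary temporal SD (um) of the search-phase
#'   separation fluctuation.
#' @param reversion_time mean-reversion timescale (s) of the confined
#'   fluctuation.
#' @param onset_separation separation (um) at or below which the motorized
#'   phase begins (when `cluster = TRUE`).
#' @param motorized_duration duration (s) of the motorized descent; the
#'   descent spans `ceiling(motorized_duration / frame_interval)` frame
#'   intervals.
#' @param final_separation clustered plateau separation (um).
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames.
#' @param anaphase_offset frames between cluster completion and anaphase
#'   onset for clustering pairs.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(cluster = TRUE,
                          mean_separation_search = if (cluster) 8.5 else 11.5,
                          sd_search = 2,
                          reversion_time = 200,
                          onset_separation = 7.5,
                          motorized_duration = 900,
                          final_separation = 1.8,
                          frame_interval = 40,
                          n_frames = 60,
                          anaphase_offset = 2,
                          seed = 1L) {
  .check_positive(mean_separation_search, "mean_separation_search")
  .check_nonneg(sd_search, "sd_search")
  .check_positive(reversion_time, "reversion_time")
  .check_positive(onset_separation, "onset_separation")
  .check_positive(motorized_duration, "motorized_duration")
  .check_positive(final_separation, "final_separation")
  .check_positive(frame_interval, "frame_interval")
  .check_positive(n_frames, "n_frames")
  if (final_separation >= onset_separation)
    stop("final_separation must be smaller than onset_separation")
  if (onset_separation > mean_separation_search)
    stop("onset_separation must not exceed mean_separation_search")
  structure(list(
    cluster = isTRUE(cluster),
    mean_separation_search = mean_separation_search,
    sd_search = sd_search,
    reversion_time = reversion_time,
    onset_separation = onset_separation,
    motorized_duration = motorized_duration,
    final_separation = final_separation,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    anaphase_offset = as.integer(anaphase_offset),
    seed = seed
  ), class = "motion_params")
}

#' Optical parameters for rendering synthetic image stacks
#'
#' Defaults follow a spinning-disk acquisition with 35 z-slices at 500 nm
#' spacing; the xy pixel size of 0.13 um corresponds to a 100x/1.45 NA
#' objective with 2x2 binning (unverified, configurable). PSF widths are
#' typical for those optics.
#'
#' @param pixel_size_xy xy pixel size (um).
#' @param z_spacing z-slice spacing (um).
#' @param n_z number of z-slices.
#' @param psf_sigma_xy lateral Gaussian PSF sigma (um).
#' @param psf_sigma_z axial Gaussian PSF sigma (um).
#' @param spot_amplitude peak spot intensity above background (photons).
#' @param background background level (photons).
#' @param noise_model `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sd read-noise SD (photons) for `"poisson+gaussian"`.
#' @param seed integer seed.
#' @return A list of class `optics_params`.
#' @export
optics_params <- function(pixel_size_xy = 0.13,
                          z_spacing = 0.5,
                          n_z = 35,
                          psf_sigma_xy = 0.11,
                          psf_sigma_z = 0.35,
                          spot_amplitude = 500,
                          background = 10,
                          noise_model = c("none", "poisson", "poisson+gaussian"),
                          gaussian_sd = 2,
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  .check_positive(pixel_size_xy, "pixel_size_xy")
  .check_positive(z_spacing, "z_spacing")
  .check_positive(n_z, "n_z")
  .check_positive(psf_sigma_xy, "psf_sigma_xy")
  .check_positive(psf_sigma_z, "psf_sigma_z")
  .check_positive(spot_amplitude, "spot_amplitude")
  .check_nonneg(background, "background")
  structure(list(
    pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
    n_z = as.integer(n_z), psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z, spot_amplitude = spot_amplitude,
    background = background, noise_model = noise_model,
    gaussian_sd = gaussian_sd, seed = seed
  ), class = "optics_params")
}

# SD of the fluctuation about the clustered plateau (um); kept well below
# the 0.1 um contract so completion detection is unambiguous
.POST_CLUSTER_SD <- 0.05

#' Simulate the biphasic separation dynamics of one centrosome pair
#'
#' Separation d(t) follows a discrete-time mean-reverting (AR(1) /
#' Ornstein-Uhlenbeck-type) process with mean `mean_separation_search`,
#' stationary SD `sd_search` and timescale `reversion_time`, reflected at
#' zero, until the first frame at which `d <= onset_separation` while
#' `cluster` is `TRUE`. From that onset frame, d decreases linearly to
#' `final_separation` over `ceiling(motorized_duration/frame_interval)`
#' frame intervals, then fluctuates about the plateau with SD well below
#' 0.1 um. 3D positions are placed symmetrically about a fixed midpoint
#' along a slowly precessing axis so that their pairwise distance equals
#' d(t) exactly.
#'
#' Anaphase onset is recorded at `completion + anaphase_offset` frames for
#' pairs that complete clustering, and 3 frames before the end of the
#' series otherwise.
#'
#' @param params a [motion_params()] object.
#' @param midpoint fixed 3D midpoint (um) of the pair axis.
#' @return A list of class `centro_truth` with elements `positions`
#'   (array `n_frames x 3 x 2`, um), `separation` (um), `time_s`,
#'   `motorized_onset_frame`, `completion_frame`, `anaphase_onset_frame`
#'   (frame indices, `NA` when absent), `onset_separation_emitted`
#'   (observed d at onset) and `params`.
#' @export
simulate_pair <- function(params = motion_params(), midpoint = c(0, 0, 0)) {
  stopifnot(inherits(params, "motion_params"), length(midpoint) == 3)
  .set_seed(params$seed)
  n <- params$n_frames
  dt <- params$frame_interval
  m <- params$mean_separation_search
  a <- exp(-dt / params$reversion_time)
  innov_sd <- params$sd_search * sqrt(1 - a^2)
  n_steps <- ceiling(params$motorized_duration / dt)

  d <- numeric(n)
  d[1] <- abs(m + stats::rnorm(1, 0, params$sd_search)) # stationary draw
  onset <- if (params$cluster && d[1] <= params$onset_separation) 1L else NA_integer_
  d_onset <- if (!is.na(onset)) d[1] else NA_real_
  if (n > 1) for (i in 2:n) {
    if (!is.na(onset)) {
      k <- i - onset
      d[i] <- if (k <= n_steps) {
        d_onset + (params$final_separation - d_onset) * k / n_steps
      } else {
        abs(params$final_separation + stats::rnorm(1, 0, .POST_CLUSTER_SD))
      }
    } else {
      d[i] <- abs(m + (d[i - 1] - m) * a + stats::rnorm(1, 0, innov_sd))
      if (params$cluster && d[i] <= params$onset_separation) {
        onset <- i
        d_onset <- d[i]
      }
    }
  }
  completion <- if (!is.na(onset) && onset + n_steps <= n) onset + n_steps else NA_integer_

  # slowly precessing unit axis; symmetric placement honours d(t) exactly
  u <- matrix(NA_real_, n, 3)
  v <- stats::rnorm(3)
  u[1, ] <- v / sqrt(sum(v^2))
  if (n > 1) for (i in 2:n) {
    v <- u[i - 1, ] + stats::rnorm(3, 0, 0.05)
    u[i, ] <- v / sqrt(sum(v^2))
  }
  positions <- array(NA_real_, dim = c(n, 3, 2),
                     dimnames = list(NULL, c("x", "y", "z"), c("A", "B")))
  positions[, , 1] <- rep(midpoint, each = n) + u * d / 2
  positions[, , 2] <- rep(midpoint, each = n) - u * d / 2

  anaphase <- if (!is.na(completion)) {
    min(n, completion + params$anaphase_offset)
  } else {
    max(1L, n - 3L)
  }
  structure(list(
    positions = positions,
    separation = d,
    time_s = (seq_len(n) - 1) * dt,
    motorized_onset_frame = onset,
    completion_frame = as.integer(completion),
    anaphase_onset_frame = as.integer(anaphase),
    onset_separation_emitted = d_onset,
    params = params
  ), class = "centro_truth")
}

#' Render a synthetic 4D image stack from pair ground truth
#'
#' Each centrosome contributes an anisotropic 3D Gaussian intensity profile
#' centred at its true position, on a constant background, with optional
#' Poisson (and Gaussian read) noise. Voxel centres sit at
#' `(i - 0.5) * spacing` for 1-based index `i`; all coordinates are in um.
#'
#' @param truth a `centro_truth` object from [simulate_pair()].
#' @param optics an [optics_params()] object.
#' @param frame_interval frame interval (s) stored with the stack; defaults
#'   to the truth's.
#' @param volume_xy_um optional c(x, y) extent (um) of the rendered volume;
#'   by default fitted to the positions plus a 2 um margin. The z extent is
#'   always `n_z * z_spacing`.
#' @return An `image_stack`: list with `data` (array `t x z x y x x`),
#'   `pixel_size_xy`, `z_spacing`, `frame_interval`.
#' @export
render_stack <- function(truth, optics = optics_params(),
                         frame_interval = NULL, volume_xy_um = NULL) {
  stopifnot(inherits(truth, "centro_truth"), inherits(optics, "optics_params"))
  .set_seed(optics$seed)
  pos <- truth$positions
  n <- dim(pos)[1]
  n_spots <- dim(pos)[3]
  px <- optics$pixel_size_xy
  zs <- optics$z_spacing
  nz <- optics$n_z
  if (is.null(volume_xy_um)) {
    volume_xy_um <- c(max(pos[, "x", ]) + 2, max(pos[, "y", ]) + 2)
  }
  nx <- ceiling(volume_xy_um[1] / px)
  ny <- ceiling(volume_xy_um[2] / px)
  z_extent <- nz * zs

  for (t in seq_len(n)) for (s in seq_len(n_spots)) {
    p <- pos[t, , s]
    if (p["x"] < 0 || p["x"] > nx * px || p["y"] < 0 || p["y"] > ny * px ||
        p["z"] < 0 || p["z"] > z_extent)
      stop(sprintf("position outside rendered volume at frame %d, centrosome %d", t, s))
  }

  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  zc <- (seq_len(nz) - 0.5) * zs
  data <- array(optics$background, dim = c(n, nz, ny, nx))
  sx <- optics$psf_sigma_xy
  sz <- optics$psf_sigma_z
  for (t in seq_len(n)) {
    for (s in seq_len(n_spots)) {
      p <- pos[t, , s]
      ix <- which(abs(xc - p["x"]) <= 6 * sx)
      iy <- which(abs(yc - p["y"]) <= 6 * sx)
      iz <- which(abs(zc - p["z"]) <= 6 * sz)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(xc[ix] - p["x"])^2 / (2 * sx^2))
      gy <- exp(-(yc[iy] - p["y"])^2 / (2 * sx^2))
      gz <- exp(-(zc[iz] - p["z"])^2 / (2 * sz^2))
      add <- optics$spot_amplitude * outer(gz, outer(gy, gx)) # z,y,x
      data[t, iz, iy, ix] <- data[t, iz, iy, ix] + add
    }
  }
  if (optics$noise_model %in% c("poisson", "poisson+gaussian")) {
    data[] <- stats::rpois(length(data), lambda = data)
    if (optics$noise_model == "poisson+gaussian")
      data[] <- data + stats::rnorm(length(data), 0, optics$gaussian_sd)
  }
  image_stack(data, pixel_size_xy = px, z_spacing = zs,
              frame_interval = frame_interval %||% truth$params$frame_interval)
}

#' Simulate tripolar spindle pole geometries
#'
#' The smallest centroid-subtended inter-pole angle of each spindle is drawn
#' from a normal distribution truncated to (0, 120] degrees. Poles are
#' placed in the plane so that the smallest angle equals the drawn value
#' exactly (angles theta, 180 - theta/2, 180 - theta/2), at a fixed 5 um
#' centroid-pole distance for the two closest poles, then randomly rotated
#' and translated (operations under which the measured angle is invariant).
#'
#' @param n number of spindles.
#' @param angle_mean mean (degrees) of the smallest-angle distribution;
#'   must lie in (0, 120].
#' @param angle_sd SD (degrees); 0 gives the mean exactly.
#' @param seed integer seed.
#' @return A list of `tripolar_spindle` objects, each with `cell_id`,
#'   `poles` (3 x 2 matrix, um) and `truth_angle` (degrees).
#' @export
simulate_tripolar <- function(n, angle_mean = 80, angle_sd = 15, seed = 1L) {
  .check_positive(n, "n")
  if (angle_mean <= 0 || angle_mean > 120)
    stop("angle_mean must lie in (0, 120] degrees")
  .check_nonneg(angle_sd, "angle_sd")
  .set_seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- angle_mean
    if (angle_sd > 0) {
      repeat {
        theta <- stats::rnorm(1, angle_mean, angle_sd)
        if (theta > 0 && theta <= 120) break
      }
    }
    th <- .deg2rad(theta)
    r <- 5
    r3 <- 2 * r * cos(th / 2)
    poles <- rbind(
      r  * c(cos(-th / 2), sin(-th / 2)),
      r  * c(cos(th / 2), sin(th / 2)),
      r3 * c(-1, 0)
    )
    rot <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    poles <- poles %*% R + matrix(stats::runif(2, -10, 10), 3, 2, byrow = TRUE)
    colnames(poles) <- c("x", "y")
    out[[i]] <- structure(
      list(cell_id = i, poles = poles, truth_angle = theta),
      class = "tripolar_spindle")
  }
  out
}

#' Parameters for simulated AFM force curves
#'
#' Defaults follow metaphase-cell indentation with a soft V-shaped
#' cantilever: nominal spring constant 0.006 N/m, approach speed 2.5 um/s,
#' conical tip of 35 degree half-angle, incompressible sample (nu = 0.5).
#'
#' @param true_modulus apparent elastic modulus (Pa) of the simulated cell.
#' @param poisson_ratio Poisson ratio (0.5 = incompressible).
#' @param tip_half_angle cone half-angle (degrees), in (0, 90).
#' @param contact_point piezo position (um) at tip-sample contact.
#' @param spring_constant cantilever spring constant (N/m).
#' @param approach_speed approach speed (um/s); metadata only.
#' @param sample_spacing piezo sampling interval (nm).
#' @param max_indentation maximum simulated indentation depth (nm).
#' @param noise_sd additive force noise SD (pN).
#' @param seed integer seed.
#' @return A list of class `afm_sim_params`.
#' @export
afm_sim_params <- function(true_modulus = 800,
                           poisson_ratio = 0.5,
                           tip_half_angle = 35,
                           contact_point = 2,
                           spring_constant = 0.006,
                           approach_speed = 2.5,
                           sample_spacing = 5,
                           max_indentation = 1500,
                           noise_sd = 20,
                           seed = 1L) {
  .check_positive(true_modulus, "true_modulus")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must lie in [0, 0.5]")
  if (tip_half_angle <= 0 || tip_half_angle >= 90)
    stop("tip_half_angle must lie in (0, 90) degrees")
  .check_positive(contact_point, "contact_point")
  .check_positive(spring_constant, "spring_constant")
  .check_positive(sample_spacing, "sample_spacing")
  .check_positive(max_indentation, "max_indentation")
  .check_nonneg(noise_sd, "noise_sd")
  structure(list(
    true_modulus = true_modulus, poisson_ratio = poisson_ratio,
    tip_half_angle = tip_half_angle, contact_point = contact_point,
    spring_constant = spring_constant, approach_speed = approach_speed,
    sample_spacing = sample_spacing, max_indentation = max_indentation,
    noise_sd = noise_sd, seed = seed
  ), class = "afm_sim_params")
}

#' Conical Sneddon force law
#'
#' `F = (2/pi) * (E / (1 - nu^2)) * tan(alpha) * delta^2`, returned in pN
#' for indentation depth in nm and modulus in Pa.
#'
#' @param delta_nm indentation depth (nm).
#' @param modulus apparent elastic modulus (Pa).
#' @param poisson_ratio Poisson ratio.
#' @param tip_half_angle cone half-angle (degrees).
#' @return Force (pN).
#' @export
sneddon_force <- function(delta_nm, modulus, poisson_ratio = 0.5,
                          tip_half_angle = 35) {
  f_n <- (2 / pi) * (modulus / (1 - poisson_ratio^2)) *
    tan(.deg2rad(tip_half_angle)) * (delta_nm * 1e-9)^2
  f_n * 1e12
}

#' Simulate an AFM approach force curve
#'
#' Before the contact point the deflection is zero-mean noise; beyond it,
#' the cantilever deflection d solves the force balance
#' `k d = Sneddon(delta)` with `delta = (z - z0) - d`, so that the emitted
#' (z, deflection) samples follow the conical Sneddon law exactly in the
#' noiseless limit. Additive force noise of SD `noise_sd` (pN) is applied
#' as equivalent deflection noise.
#'
#' @param params an [afm_sim_params()] object.
#' @param position_id,cell_id identifiers stored with the curve.
#' @return A `force_curve`: list with `piezo_z_um`, `deflection` (nm),
#'   `deflection_unit`, `spring_constant` (N/m), `sensitivity` (nm/V or
#'   `NA`), `position_id`, `cell_id`, and a `truth` list.
#' @export
simulate_force_curve <- function(params = afm_sim_params(),
                                 position_id = "p1", cell_id = "c1") {
  stopifnot(inherits(params, "afm_sim_params"))
  .set_seed(params$seed)
  k <- params$spring_constant
  C <- (2 / pi) * (params$true_modulus / (1 - params$poisson_ratio^2)) *
    tan(.deg2rad(params$tip_half_angle)) # Pa-scale prefactor, SI
  delta_max <- params$max_indentation * 1e-9
  d_max <- C * delta_max^2 / k
  z_end <- params$contact_point + (delta_max + d_max) * 1e6
  z <- seq(0, z_end, by = params$sample_spacing * 1e-3) # um
  w <- pmax(z - params$contact_point, 0) * 1e-6 # m beyond contact
  # C delta^2 + k delta - k w = 0  =>  physical root
  delta <- ifelse(w > 0, (-k + sqrt(k^2 + 4 * C * k * w)) / (2 * C), 0)
  d_nm <- (w - delta) * 1e9
  if (params$noise_sd > 0)
    d_nm <- d_nm + stats::rnorm(length(z), 0, params$noise_sd * 1e-3 / k)
  structure(list(
    piezo_z_um = z,
    deflection = d_nm,
    deflection_unit = "nm",
    spring_constant = k,
    sensitivity = NA_real_,
    position_id = position_id,
    cell_id = cell_id,
    truth = list(modulus = params$true_modulus,
                 contact_point = params$contact_point),
    params = params
  ), class = "force_curve")
}
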