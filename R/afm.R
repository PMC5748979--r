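# deflection in nm, converting from volts via the sensitivity when needed
.deflection_nm <- function(curve) {
  if (identical(curve$deflection_unit, "nm")) return(curve$deflection)
  if (identical(curve$deflection_unit, "V")) {
    if (is.null(curve$sensitivity) || is.na(curve$sensitivity))
      stop("deflection is in volts but the curve carries no sensitivity (nm/V)")
    return(curve$deflection * curve$sensitivity)
  }
  stop("unknown deflection unit: ", curve$deflection_unit)
}

#' Construct an AFM force curve object
#'
#' @param piezo_z_um piezo displacement samples (um), strictly increasing
#'   on the approach.
#' @param deflection cantilever deflection samples (nm or V).
#' @param spring_constant cantilever spring constant (N/m).
#' @param deflection_unit `"nm"` or `"V"`.
#' @param sensitivity optical lever sensitivity (nm/V); required to
#'   interpret deflections in volts.
#' @param position_id,cell_id identifiers.
#' @return A list of class `force_curve`.
#' @export
force_curve <- function(piezo_z_um, deflection, spring_constant,
                        deflection_unit = "nm", sensitivity = NA_real_,
                        position_id = "p1", cell_id = "c1") {
  stopifnot(length(piezo_z_um) == length(deflection))
  if (any(diff(piezo_z_um) <= 0))
    stop("piezo_z_um must be strictly increasing on the approach segment")
  .check_positive(spring_constant, "spring_constant")
  structure(list(piezo_z_um = piezo_z_um, deflection = deflection,
                 deflection_unit = deflection_unit,
                 spring_constant = spring_constant,
                 sensitivity = sensitivity, position_id = position_id,
                 cell_id = cell_id),
            class = "force_curve")
}

#' Cantilever sensitivity from a glass (rigid substrate) curve
#'
#' On a rigid substrate the tip does not indent, so beyond contact the
#' deflection rises one-for-one with the piezo displacement; the
#' sensitivity is the inverse slope of the post-contact linear region
#' (robust line fit), expressed as nm of piezo travel per deflection unit.
#' For a curve already in matched units the returned value is 1.
#'
#' @param curve a [force_curve()] acquired on glass.
#' @return Sensitivity (nm per deflection unit, i.e. nm/V for raw volts).
#' @export
sensitivity_from_glass <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  d <- curve$deflection
  z_nm <- curve$piezo_z_um * 1000
  n <- length(d)
  base <- d[seq_len(max(5, floor(0.2 * n)))]
  thr <- stats::median(base) + 5 * stats::mad(base)
  post <- which(d > thr)
  if (length(post) < 5)
    stop("no post-contact linear region found")
  # use the upper part of the rise, away from the contact transition
  post <- post[d[post] >= stats::quantile(d[post], 0.4)]
  if (length(post) < 5) stop("no post-contact linear region found")
  fit <- suppressWarnings(MASS::rlm(d[post] ~ z_nm[post], maxit = 50))
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope <= 0) stop("no post-contact linear region found")
  1 / as.numeric(slope)
}

#' Locate the tip-sample contact point of a force curve
#'
#' Scans candidate contact points on the sampled piezo grid; each candidate
#' scores the summed squared residuals of a flat baseline fitted before it
#' plus a Sneddon-form fit (`F = a * delta^2`, `delta = (z - z0) - d`)
#' after it. The minimizing candidate is refined by parabolic
#' interpolation of the residual profile. Errors when the residual profile
#' shows no contact (flat or pure-noise curves).
#'
#' @param curve a [force_curve()].
#' @param min_post minimum number of post-contact samples.
#' @return Contact point z0 (um).
#' @export
find_contact_point <- function(curve, min_post = 10) {
  stopifnot(inherits(curve, "force_curve"))
  d_nm <- .deflection_nm(curve)
  z <- curve$piezo_z_um
  k <- curve$spring_constant
  f_pn <- k * d_nm * 1000
  n <- length(z)
  if (n < min_post + 5) stop("curve too short")
  cands <- 3:(n - min_post)
  f_cum <- cumsum(f_pn); f2_cum <- cumsum(f_pn^2)
  sse <- rep(NA_real_, length(cands))
  for (qi in seq_along(cands)) {
    i <- cands[qi]
    # baseline over [1, i]: SSE about the mean via running sums
    sse_base <- f2_cum[i] - f_cum[i]^2 / i
    post <- (i + 1):n
    delta <- (z[post] - z[i]) * 1000 - d_nm[post]
    pos <- delta > 0
    if (sum(pos) < min_post) next
    dd <- delta[pos]; ff <- f_pn[post][pos]
    a <- max(0, sum(dd^2 * ff) / sum(dd^4))
    sse[qi] <- sse_base + sum((ff - a * dd^2)^2) +
      sum(f_pn[post][!pos]^2)
  }
  if (all(is.na(sse))) stop("no contact point found")
  sse_flat <- f2_cum[n] - f_cum[n]^2 / n
  qb <- which.min(sse)
  if (sse_flat <= 0 || (1 - sse[qb] / sse_flat) < 0.2)
    stop("no contact detected: residual profile is flat")
  z0 <- z[cands[qb]]
  # parabolic refinement on the residual profile
  if (qb > 1 && qb < length(sse) &&
      all(is.finite(sse[(qb - 1):(qb + 1)]))) {
    y1 <- sse[qb - 1]; y2 <- sse[qb]; y3 <- sse[qb + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) {
      shift <- 0.5 * (y1 - y3) / denom
      shift <- max(-1, min(1, shift))
      step <- z[cands[qb] + 1] - z[cands[qb]]
      z0 <- z0 + shift * step
    }
  }
  z0
}

#' Force-indentation series beyond the contact point
#'
#' For samples beyond z0 the indentation is the piezo travel past contact
#' minus the cantilever deflection, `delta = (z - z0) - d`, and the force
#' is `F = k * d`. Samples with negative indentation are dropped.
#'
#' @param curve a [force_curve()].
#' @param z0 contact point (um), within the curve's range.
#' @return A data.frame: `delta_nm`, `force_pN`.
#' @export
indentation_force <- function(curve, z0) {
  stopifnot(inherits(curve, "force_curve"))
  if (z0 < min(curve$piezo_z_um) || z0 > max(curve$piezo_z_um))
    stop("z0 outside the curve's piezo range")
  d_nm <- .deflection_nm(curve)
  post <- curve$piezo_z_um > z0
  delta <- (curve$piezo_z_um[post] - z0) * 1000 - d_nm[post]
  force <- curve$spring_constant * d_nm[post] * 1000
  keep <- delta >= 0
  data.frame(delta_nm = delta[keep], force_pN = force[keep])
}

#' Average several force-indentation curves from one position
#'
#' Curves are resampled by linear interpolation onto a common indentation
#' grid spanning the overlap of their ranges and averaged pointwise.
#'
#' @param curves list of data.frames (`delta_nm`, `force_pN`).
#' @param n_grid number of grid points.
#' @return A data.frame (`delta_nm`, `force_pN`) with attribute
#'   `n_curves`.
#' @export
average_position_curves <- function(curves, n_grid = 200) {
  if (!length(curves)) stop("at least one curve is required")
  curves <- lapply(curves, as.data.frame)
  lo <- max(vapply(curves, function(c) min(c$delta_nm), numeric(1)))
  hi <- min(vapply(curves, function(c) max(c$delta_nm), numeric(1)))
  if (hi <= lo) stop("curves have disjoint indentation ranges")
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(curves, function(c)
    stats::approx(c$delta_nm, c$force_pN, xout = grid, ties = mean)$y,
    numeric(n_grid))
  out <- data.frame(delta_nm = grid, force_pN = rowMeans(as.matrix(mat)))
  attr(out, "n_curves") <- length(curves)
  out
}

#' Fit the conical Sneddon model to a force-indentation curve
#'
#' Least-squares fit of `F = (2/pi) * (E / (1 - nu^2)) * tan(alpha) *
#' delta^2` restricted to indentation depths in (0, `max_depth`\] - shallow
#' depths emphasize the cortex's contribution to the restoring force over
#' the cytoplasm's.
#'
#' @param delta_force data.frame (`delta_nm`, `force_pN`).
#' @param max_depth maximum indentation depth used in the fit (nm).
#' @param tip_half_angle cone half-angle alpha (degrees).
#' @param poisson_ratio Poisson ratio nu.
#' @param position_id identifier carried into the estimate.
#' @return A list of class `elasticity_estimate`: `position_id`,
#'   `apparent_modulus` (Pa), `fit_rms` (pN), `depth_used` (nm),
#'   `n_samples`, `n_curves_averaged`.
#' @export
fit_sneddon <- function(delta_force, max_depth = 800, tip_half_angle = 35,
                        poisson_ratio = 0.5, position_id = "p1") {
  df <- as.data.frame(delta_force)
  sel <- df$delta_nm > 0 & df$delta_nm <= max_depth
  if (sum(sel) < 10)
    stop("fewer than 10 samples at indentation depths within max_depth")
  dd <- df$delta_nm[sel]; ff <- df$force_pN[sel]
  beta <- sum(dd^2 * ff) / sum(dd^4) # pN / nm^2
  if (!is.finite(beta) || beta <= 0) stop("Sneddon fit failed: non-positive modulus")
  e_pa <- beta * 1e6 * pi * (1 - poisson_ratio^2) /
    (2 * tan(.deg2rad(tip_half_angle)))
  resid <- ff - beta * dd^2
  structure(list(position_id = position_id,
                 apparent_modulus = e_pa,
                 fit_rms = sqrt(mean(resid^2)),
                 depth_used = max(dd),
                 n_samples = sum(sel),
                 n_curves_averaged = attr(delta_force, "n_curves") %||% 1L),
            class = "elasticity_estimate")
}

#' Apparent elasticity of one probed curve, end to end
#'
#' Convenience wrapper: contact point, force-indentation conversion, and
#' depth-restricted Sneddon fit.
#'
#' @param curve a [force_curve()].
#' @inheritParams fit_sneddon
#' @return An `elasticity_estimate` with the `contact_point` recorded.
#' @export
process_force_curve <- function(curve, max_depth = 800, tip_half_angle = 35,
                                poisson_ratio = 0.5) {
  z0 <- find_contact_point(curve)
  est <- fit_sneddon(indentation_force(curve, z0), max_depth = max_depth,
                     tip_half_angle = tip_half_angle,
                     poisson_ratio = poisson_ratio,
                     position_id = curve$position_id)
  est$contact_point <- z0
  est$cell_id <- curve$cell_id
  est
}

#' Per-cell summary of position moduli
#'
#' @param estimates list of `elasticity_estimate` objects carrying
#'   `cell_id`, or a data.frame with columns `cell_id`,
#'   `apparent_modulus`.
#' @return A data.frame: `cell_id`, `mean_modulus`, `sd_modulus`,
#'   `n_positions`.
#' @export
cell_elasticity <- function(estimates) {
  df <- if (is.data.frame(estimates)) estimates else
    do.call(rbind, lapply(estimates, function(e)
      data.frame(cell_id = e$cell_id %||% "c1",
                 apparent_modulus = e$apparent_modulus)))
  out <- do.call(rbind, lapply(split(df, df$cell_id), function(g)
    data.frame(cell_id = g$cell_id[1],
               mean_modulus = mean(g$apparent_modulus),
               sd_modulus = if (nrow(g) >= 2) stats::sd(g$apparent_modulus) else NA_real_,
               n_positions = nrow(g))))
  rownames(out) <- NULL
  out
}

#' Write / read a force curve as TSV with JSON metadata
#'
#' @param curve a [force_curve()].
#' @param path TSV output path (`z_um`, `deflection`); metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.table(
    data.frame(z_um = curve$piezo_z_um, deflection = curve$deflection),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(spring_constant = curve$spring_constant,
               deflection_unit = curve$deflection_unit,
               sensitivity = curve$sensitivity,
               position_id = curve$position_id, cell_id = curve$cell_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  force_curve(df$z_um, df$deflection,
              spring_constant = meta$spring_constant,
              deflection_unit = meta$deflection_unit %||% "nm",
              sensitivity = meta$sensitivity %||% NA_real_,
              position_id = meta$position_id %||% "p1",
              cell_id = meta$cell_id %||% "c1")
}
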