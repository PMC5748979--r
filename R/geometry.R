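#' Inter-pole angles of a tripolar spindle, subtended at the pole centroid
#'
#' @param poles 3 x 2 or 3 x 3 matrix of pole coordinates (um), or a
#'   `tripolar_spindle`.
#' @return Numeric vector of the three centroid-subtended angles (degrees);
#'   they sum to 360.
#' @export
pole_angles <- function(poles) {
  if (inherits(poles, "tripolar_spindle")) poles <- poles$poles
  poles <- as.matrix(poles)
  if (nrow(poles) != 3 || !ncol(poles) %in% c(2, 3))
    stop("poles must be a 3 x 2 or 3 x 3 coordinate matrix")
  if (ncol(poles) == 2) poles <- cbind(poles, 0)
  scale <- max(.row_dist(poles, poles[c(2, 3, 1), , drop = FALSE]))
  if (scale < 1e-12) stop("degenerate spindle: coincident poles")
  e1 <- poles[2, ] - poles[1, ]
  e2 <- poles[3, ] - poles[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(cr^2)) < 1e-6 * scale^2)
    stop("degenerate spindle: collinear poles")
  ctr <- colMeans(poles)
  v <- sweep(poles, 2, ctr)
  ang <- function(a, b) {
    cosv <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    .rad2deg(acos(pmin(1, pmax(-1, cosv))))
  }
  c(ang(v[1, ], v[2, ]), ang(v[1, ], v[3, ]), ang(v[2, ], v[3, ]))
}

#' Smallest inter-pole angle of a tripolar spindle
#'
#' The three poles subtend three angles at their centroid (summing to 360
#' degrees); the smallest, necessarily at most 120 degrees, measures how
#' close the two closest poles are - the proxy for centrosome proximity in
#' tripolar metaphases.
#'
#' @inheritParams pole_angles
#' @return The smallest centroid-subtended angle (degrees).
#' @export
smallest_pole_angle <- function(poles) min(pole_angles(poles))

#' Angular (rose-plot) histogram of smallest inter-pole angles
#'
#' Bins angles in right-open bins of `bin_width` degrees from 0 (the last
#' bin is closed so 120 is included) and reports the mean angle.
#'
#' @param angles smallest inter-pole angles (degrees), each in (0, 120].
#' @param bin_width bin width (degrees).
#' @return A list of class `rose_histogram`: `breaks`, `counts`, `mids`,
#'   `mean_angle`, `n`.
#' @export
rose_histogram <- function(angles, bin_width = 10) {
  .check_positive(bin_width, "bin_width")
  bad <- which(angles <= 0 | angles > 120)
  if (length(bad))
    stop(sprintf("angle out of (0, 120]: %s", paste(round(angles[bad], 3), collapse = ", ")))
  breaks <- seq(0, ceiling(120 / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(angles, breaks = breaks, right = FALSE, plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 mean_angle = mean(angles), n = length(angles)),
            class = "rose_histogram")
}

#' Centrosome clustering efficiency with a Wilson confidence interval
#'
#' Fraction of divisions with supernumerary centrioles that are bipolar
#' (clustered), with the Wilson score interval.
#'
#' @param n_bipolar_clustered number of bipolar clustered divisions.
#' @param n_total total divisions scored, > 0.
#' @param conf_level confidence level.
#' @return A list: `fraction`, `ci_lower`, `ci_upper`, `n`.
#' @export
clustering_efficiency <- function(n_bipolar_clustered, n_total,
                                  conf_level = 0.95) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_bipolar_clustered < 0 || n_bipolar_clustered > n_total)
    stop("n_bipolar_clustered must lie in [0, n_total]")
  ci <- stats::prop.test(n_bipolar_clustered, n_total,
                         conf.level = conf_level, correct = FALSE)$conf.int
  list(fraction = n_bipolar_clustered / n_total,
       ci_lower = ci[1], ci_upper = ci[2], n = n_total)
}

#' Read a pole-coordinate table
#'
#' Expects columns `cell_id`, `pole_index`, `x_um`, `y_um`, optionally
#' `z_um` and `condition`.
#'
#' @param path CSV path.
#' @return A list of `tripolar_spindle` objects.
#' @export
read_pole_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "pole_index", "x_um", "y_um") %in% names(df)))
  lapply(split(df, df$cell_id), function(g) {
    g <- g[order(g$pole_index), ]
    if (nrow(g) != 3) stop(sprintf("cell %s does not have 3 poles", g$cell_id[1]))
    cols <- intersect(c("x_um", "y_um", "z_um"), names(g))
    structure(list(cell_id = g$cell_id[1],
                   poles = as.matrix(g[, cols]),
                   condition_label = if ("condition" %in% names(g))
                     g$condition[1] else NA_character_),
              class = "tripolar_spindle")
  })
}
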