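#' Gating mask radius for frame-wise spot association
#'
#' `r = 2 * dt * v_avg`: twice the distance a centrosome moving at the
#' mean absolute speed covers in one frame interval. With dt = 40 s and
#' v_avg = 0.02 um/s this gives 1.6 um.
#'
#' @param frame_interval frame interval dt (s), > 0.
#' @param mean_speed mean absolute centrosome speed v_avg (um/s), > 0.
#' @return Mask radius (um).
#' @export
mask_radius <- function(frame_interval, mean_speed) {
  .check_positive(frame_interval, "frame_interval")
  .check_positive(mean_speed, "mean_speed")
  2 * frame_interval * mean_speed
}

#' Build the anchor-frame propagation plan
#'
#' Every non-anchor frame is assigned to its nearest anchor frame (ties
#' toward the earlier anchor) and is seeded from the adjacent frame one
#' step closer to that anchor. E.g. with anchors \{1, 6\}: 2 from 1, 3 from
#' 2, 4 from 5, 5 from 6.
#'
#' @param anchor_frames strictly increasing anchor frame indices (1-based).
#' @param n_frames total number of frames.
#' @return A list of class `propagation_plan`: `anchor_frames`, `source_of`
#'   (named integer vector over non-anchor frames), `direction_of`
#'   (`"anchor"`, `"forward"` or `"backward"` per frame), `order` (frames
#'   in a processing order in which every source precedes its target).
#' @export
build_plan <- function(anchor_frames, n_frames) {
  anchor_frames <- as.integer(anchor_frames)
  n_frames <- as.integer(n_frames)
  if (!length(anchor_frames)) stop("at least one anchor frame is required")
  if (any(diff(anchor_frames) <= 0)) stop("anchor frames must be strictly increasing")
  if (min(anchor_frames) < 1 || max(anchor_frames) > n_frames)
    stop("anchor frames out of range")
  frames <- seq_len(n_frames)
  nearest <- vapply(frames, function(f) {
    d <- abs(anchor_frames - f)
    anchor_frames[which.min(d)] # first min = earlier anchor on ties
  }, integer(1))
  is_anchor <- frames %in% anchor_frames
  source_of <- integer(0)
  direction_of <- ifelse(is_anchor, "anchor",
                         ifelse(frames > nearest, "forward", "backward"))
  non_anchor <- frames[!is_anchor]
  src <- ifelse(non_anchor > nearest[non_anchor], non_anchor - 1L, non_anchor + 1L)
  source_of <- stats::setNames(as.integer(src), non_anchor)
  ord <- frames[order(abs(frames - nearest), frames)]
  structure(list(anchor_frames = anchor_frames, source_of = source_of,
                 direction_of = stats::setNames(direction_of, frames),
                 order = ord, n_frames = n_frames),
            class = "propagation_plan")
}

# exact minimum-total-distance one-to-one assignment under a gate.
# cost: n_src x n_det matrix; returns integer vector over sources
# (detection index or NA). Maximizes the number of matches, then
# minimizes total distance; exact branch-and-bound (spot counts are tiny).
.gated_assignment <- function(cost, gate) {
  ns <- nrow(cost); nd <- ncol(cost)
  if (ns == 0 || nd == 0) return(rep(NA_integer_, ns))
  feasible <- cost <= gate
  best <- list(n = -1L, total = Inf, assign = rep(NA_integer_, ns))
  assign <- rep(NA_integer_, ns)
  used <- rep(FALSE, nd)
  recurse <- function(i, n_matched, total) {
    if (i > ns) {
      if (n_matched > best$n ||
          (n_matched == best$n && total < best$total)) {
        best <<- list(n = n_matched, total = total, assign = assign)
      }
      return(invisible(NULL))
    }
    # bound: even matching everything remaining cannot beat best
    remaining <- ns - i + 1L
    if (n_matched + remaining < best$n) return(invisible(NULL))
    opts <- which(feasible[i, ] & !used)
    for (j in opts[order(cost[i, opts])]) {
      assign[i] <<- j; used[j] <<- TRUE
      recurse(i + 1L, n_matched + 1L, total + cost[i, j])
      assign[i] <<- NA_integer_; used[j] <<- FALSE
    }
    recurse(i + 1L, n_matched, total) # leave source i unmatched
  }
  recurse(1L, 0L, 0)
  best$assign
}

#' Link per-frame spot detections into trajectories
#'
#' Associates detections between adjacent frames by exact globally optimal
#' one-to-one nearest-neighbour assignment under the gate radius (the
#' result is independent of input spot order). A trajectory missing a
#' detection carries its last position for up to `max_gap` frames; if it is
#' re-detected within the gap, the missing frames are filled by linear
#' interpolation and flagged; longer gaps terminate the trajectory.
#' Detections that no existing trajectory claims start new trajectories.
#'
#' @param spots_by_frame a data.frame with columns `frame`, `x_um`, `y_um`,
#'   `z_um` (extra columns preserved), or a list of such per frame.
#' @param radius gate radius (um); see [mask_radius()].
#' @param frame_interval frame interval (s) used for the `time_s` column.
#' @param max_gap maximum number of interpolated frames.
#' @param plan optional [build_plan()] output, recorded as an attribute for
#'   audit (association itself is adjacent-frame, as in the plan's chains).
#' @return A list of trajectory data.frames (columns `centrosome_id`,
#'   `frame`, `time_s`, `x_um`, `y_um`, `z_um`, `interpolated`), ordered by
#'   id.
#' @export
link <- function(spots_by_frame, radius, frame_interval = 40, max_gap = 2,
                 plan = NULL) {
  .check_positive(radius, "radius")
  if (is.list(spots_by_frame) && !is.data.frame(spots_by_frame))
    spots_by_frame <- do.call(rbind, spots_by_frame)
  df <- as.data.frame(spots_by_frame)
  stopifnot(all(c("frame", "x_um", "y_um", "z_um") %in% names(df)))
  frames <- sort(unique(df$frame))
  # deterministic detection order within each frame
  df <- df[order(df$frame, df$x_um, df$y_um, df$z_um), ]

  tracks <- list() # each: list(id, rows = data.frame, gap, last)
  done <- list()
  next_id <- 1L
  prev_frame <- NULL
  for (f in frames) {
    det <- df[df$frame == f, , drop = FALSE]
    gap_step <- if (is.null(prev_frame)) 1L else f - prev_frame
    if (length(tracks) && gap_step > 1L) {
      # age active tracks by skipped frames; retire those past the max gap
      for (k in seq_along(tracks)) tracks[[k]]$gap <- tracks[[k]]$gap + gap_step - 1L
      expired <- vapply(tracks, function(tr) tr$gap > max_gap, logical(1))
      done <- c(done, tracks[expired])
      tracks <- tracks[!expired]
    }
    if (length(tracks)) {
      preds <- do.call(rbind, lapply(tracks, function(tr) tr$last))
      cost <- sqrt(outer(preds[, 1], det$x_um, "-")^2 +
                   outer(preds[, 2], det$y_um, "-")^2 +
                   outer(preds[, 3], det$z_um, "-")^2)
      cost <- matrix(cost, nrow = length(tracks))
      asg <- .gated_assignment(cost, radius)
    } else {
      asg <- integer(0)
    }
    matched_det <- asg[!is.na(asg)]
    keep <- logical(length(tracks))
    for (k in seq_along(tracks)) {
      j <- if (k <= length(asg)) asg[k] else NA_integer_
      if (!is.na(j)) {
        tr <- tracks[[k]]
        if (tr$gap > 0) { # fill the gap by linear interpolation
          last_row <- tr$rows[nrow(tr$rows), ]
          miss <- (last_row$frame + 1):(f - 1)
          frac <- (miss - last_row$frame) / (f - last_row$frame)
          fill <- data.frame(
            frame = miss,
            x_um = last_row$x_um + frac * (det$x_um[j] - last_row$x_um),
            y_um = last_row$y_um + frac * (det$y_um[j] - last_row$y_um),
            z_um = last_row$z_um + frac * (det$z_um[j] - last_row$z_um),
            interpolated = TRUE)
          tr$rows <- rbind(tr$rows, fill)
        }
        tr$rows <- rbind(tr$rows, data.frame(
          frame = f, x_um = det$x_um[j], y_um = det$y_um[j],
          z_um = det$z_um[j], interpolated = FALSE))
        tr$last <- c(det$x_um[j], det$y_um[j], det$z_um[j])
        tr$gap <- 0L
        tracks[[k]] <- tr
        keep[k] <- TRUE
      } else {
        tracks[[k]]$gap <- tracks[[k]]$gap + 1L
        if (tracks[[k]]$gap > max_gap) {
          done[[length(done) + 1L]] <- tracks[[k]]
        } else {
          keep[k] <- TRUE
        }
      }
    }
    tracks <- tracks[keep]
    unmatched <- setdiff(seq_len(nrow(det)), matched_det)
    for (j in unmatched) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id,
        rows = data.frame(frame = f, x_um = det$x_um[j], y_um = det$y_um[j],
                          z_um = det$z_um[j], interpolated = FALSE),
        gap = 0L, last = c(det$x_um[j], det$y_um[j], det$z_um[j]))
      next_id <- next_id + 1L
    }
    prev_frame <- f
  }
  all_tracks <- c(done, tracks)
  all_tracks <- all_tracks[order(vapply(all_tracks, `[[`, integer(1), "id"))]
  out <- lapply(all_tracks, function(tr) {
    rows <- tr$rows
    rows$centrosome_id <- tr$id
    rows$time_s <- (rows$frame - 1) * frame_interval
    rows[, c("centrosome_id", "frame", "time_s", "x_um", "y_um", "z_um",
             "interpolated")]
  })
  attr(out, "plan") <- plan
  attr(out, "gate_radius_um") <- radius
  out
}

#' Track all spots in a stack by anchor propagation and gated linking
#'
#' End-to-end tracker: spots are seeded at anchor frames ([seed_anchor()]),
#' every other frame is searched within a spherical mask centred on the
#' spots of its plan source frame ([detect_in_mask()]), all detections are
#' refined by 3D Gaussian fitting ([fit_gaussian_3d()]), and trajectories
#' are assembled by gated global nearest-neighbour assignment ([link()]).
#'
#' @param stack an [image_stack()].
#' @param anchor_frames anchor frame indices; default every 6th frame.
#' @param seeds optional data.frame of click coordinates (`frame`, `x_um`,
#'   `y_um`) replayed at anchor frames instead of auto-detection.
#' @param mean_speed mean centrosome speed (um/s) for [mask_radius()].
#' @param max_gap maximum interpolated gap (frames).
#' @param refine logical; run the Gaussian refinement (default) or keep
#'   voxel-level centres.
#' @return As [link()], with attributes `spots` (the detection table),
#'   `plan` and `gate_radius_um`.
#' @export
track_stack <- function(stack, anchor_frames = NULL, seeds = NULL,
                        mean_speed = 0.02, max_gap = 2, refine = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$data)[1]
  if (is.null(anchor_frames)) anchor_frames <- seq(1L, n, by = 6L)
  plan <- build_plan(anchor_frames, n)
  gate <- mask_radius(stack$frame_interval, mean_speed)
  centers_by_frame <- vector("list", n)
  refine_one <- function(frame, ctr, src) {
    if (!refine) {
      return(data.frame(frame = frame, x_um = ctr[1], y_um = ctr[2],
                        z_um = ctr[3], amplitude = NA_real_,
                        residual = NA_real_, source = src))
    }
    obs <- fit_gaussian_3d(stack, frame, ctr, source = src)
    data.frame(frame = frame, x_um = obs$center[1], y_um = obs$center[2],
               z_um = obs$center[3], amplitude = obs$amplitude,
               residual = obs$fit_residual, source = src)
  }
  for (f in plan$order) {
    if (plan$direction_of[[f]] == "anchor") {
      ctrs <- if (!is.null(seeds)) {
        s <- seeds[seeds$frame == f, , drop = FALSE]
        seed_anchor(stack, f, mode = "provided", seeds = s)
      } else {
        seed_anchor(stack, f, mode = "auto")
      }
      if (nrow(ctrs)) {
        centers_by_frame[[f]] <- do.call(rbind, lapply(seq_len(nrow(ctrs)),
          function(i) refine_one(f, ctrs[i, ], "anchor-seed")))
      }
    } else {
      src <- plan$source_of[[as.character(f)]]
      src_spots <- centers_by_frame[[src]]
      if (is.null(src_spots) || !nrow(src_spots)) next
      found <- list()
      for (i in seq_len(nrow(src_spots))) {
        ctr <- detect_in_mask(stack, f,
                              c(src_spots$x_um[i], src_spots$y_um[i],
                                src_spots$z_um[i]), gate)
        if (!is.null(ctr)) found[[length(found) + 1L]] <- ctr
      }
      if (length(found)) {
        vox <- unique(do.call(rbind, found)) # two sources may hit one voxel
        centers_by_frame[[f]] <- do.call(rbind, lapply(seq_len(nrow(vox)),
          function(i) refine_one(f, vox[i, ], "propagated")))
      }
    }
  }
  spots <- do.call(rbind, centers_by_frame[!vapply(centers_by_frame, is.null,
                                                   logical(1))])
  if (is.null(spots) || !nrow(spots)) {
    warning("no spots detected in stack")
    out <- list()
    attr(out, "plan") <- plan
    attr(out, "gate_radius_um") <- gate
    attr(out, "spots") <- spots
    return(out)
  }
  out <- link(spots, radius = gate, frame_interval = stack$frame_interval,
              max_gap = max_gap, plan = plan)
  attr(out, "spots") <- spots
  out
}
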