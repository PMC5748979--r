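#' Pair separation series from two trajectories
#'
#' 3D Euclidean distance between two trajectories at each common frame.
#' Frames where either observation was interpolated are flagged through.
#'
#' @param trajA,trajB trajectory data.frames from [link()] (columns
#'   `frame`, `time_s`, `x_um`, `y_um`, `z_um`, optionally `interpolated`).
#' @param pair_id identifier for the pair.
#' @param condition_label optional condition label.
#' @param anaphase_onset_frame optional anaphase onset annotation (frame).
#' @return A list of class `separation_series`: data in `$data` (columns
#'   `frame`, `time_s`, `d_um`, `interpolated`), plus `pair_id`,
#'   `condition_label`, `anaphase_onset_frame`, `frame_interval`.
#' @export
separation_series <- function(trajA, trajB, pair_id = "pair1",
                              condition_label = NA_character_,
                              anaphase_onset_frame = NA_integer_) {
  a <- as.data.frame(trajA); b <- as.data.frame(trajB)
  common <- intersect(a$frame, b$frame)
  if (length(common) < 3) stop("trajectories share fewer than 3 common frames")
  common <- sort(common)
  ia <- match(common, a$frame); ib <- match(common, b$frame)
  d <- sqrt((a$x_um[ia] - b$x_um[ib])^2 + (a$y_um[ia] - b$y_um[ib])^2 +
              (a$z_um[ia] - b$z_um[ib])^2)
  interp <- (if ("interpolated" %in% names(a)) a$interpolated[ia] else FALSE) |
    (if ("interpolated" %in% names(b)) b$interpolated[ib] else FALSE)
  tm <- if ("time_s" %in% names(a)) a$time_s[ia] else (common - 1) * 40
  dt <- if (length(common) > 1) stats::median(diff(tm) / diff(common)) else NA_real_
  structure(list(
    data = data.frame(frame = common, time_s = tm, d_um = d,
                      interpolated = interp),
    pair_id = pair_id, condition_label = condition_label,
    anaphase_onset_frame = anaphase_onset_frame, frame_interval = dt
  ), class = "separation_series")
}

#' Separation series from simulated ground truth
#'
#' Convenience constructor turning a `centro_truth` object into the
#' `separation_series` the kinematics operations consume, carrying the
#' truth's anaphase annotation.
#'
#' @param truth a `centro_truth` from [simulate_pair()].
#' @param pair_id,condition_label identifiers.
#' @return A `separation_series`.
#' @export
truth_separation <- function(truth, pair_id = "pair1",
                             condition_label = NA_character_) {
  stopifnot(inherits(truth, "centro_truth"))
  n <- length(truth$separation)
  structure(list(
    data = data.frame(frame = seq_len(n), time_s = truth$time_s,
                      d_um = truth$separation, interpolated = FALSE),
    pair_id = pair_id, condition_label = condition_label,
    anaphase_onset_frame = truth$anaphase_onset_frame,
    frame_interval = truth$params$frame_interval
  ), class = "separation_series")
}

#' @export
print.separation_series <- function(x, ...) {
  cat(sprintf("separation_series '%s': %d frames, d in [%.2f, %.2f] um\n",
              x$pair_id, nrow(x$data), min(x$data$d_um), max(x$data$d_um)))
  invisible(x)
}

#' @export
plot.separation_series <- function(x, ...) {
  graphics::plot(x$data$time_s / 60, x$data$d_um, type = "l",
                 xlab = "time (min)", ylab = "separation d (um)",
                 main = x$pair_id, ...)
  invisible(x)
}

#' Detect cluster completion: the time point at which separation stabilizes
#'
#' Returns the earliest frame `t_c` such that (i) `d(t) <= d_clustered`
#' for every `t >= t_c` and (ii) the SD of d over every window of
#' `stability_window` frames starting at or after `t_c` is at most
#' `stability_sd` (trailing windows shorter than the window length are
#' evaluated over the available frames). `NA` if no such frame exists.
#'
#' @param series a [separation_series()].
#' @param d_clustered separation threshold (um) for the clustered state.
#' @param stability_window window length (frames) of the stability test.
#' @param stability_sd maximum SD (um) within each window.
#' @return Completion frame index, or `NA_integer_`.
#' @export
detect_completion <- function(series, d_clustered = 2, stability_window = 5,
                              stability_sd = 0.3) {
  stopifnot(inherits(series, "separation_series"))
  d <- series$data$d_um
  n <- length(d)
  if (n < stability_window) {
    warning("series shorter than stability window")
    return(NA_integer_)
  }
  suffix_max <- rev(cummax(rev(d)))
  ok_thr <- suffix_max <= d_clustered
  if (!any(ok_thr)) return(NA_integer_)
  t0 <- which(ok_thr)[1]
  sds <- .rolling_sd_from(d, stability_window)
  bad <- which(sds > stability_sd)
  t_c <- if (length(bad)) max(t0, max(bad) + 1L) else t0
  if (t_c > n) return(NA_integer_)
  series$data$frame[t_c]
}

#' Segment a clustering trajectory into search-and-capture and motorized phases
#'
#' Fits, over the window from the series start to the completion frame, the
#' two-piece model \{constant plateau -> linear descent anchored at
#' (completion, d(completion))\}: for each candidate changepoint the
#' plateau level is the mean of d up to and including the changepoint, the
#' descent is the least-squares line through the completion point fitted
#' from the changepoint onward (the changepoint sample contributes to both
#' pieces), and the changepoint minimizing the total squared error is the
#' motorized onset. Ties break toward the earliest changepoint. A
#' non-negative descent slope rejects the segmentation.
#'
#' @param series a [separation_series()].
#' @param completion completion frame index (from [detect_completion()]).
#' @return A list of class `phase_segmentation`: `segmentable`,
#'   `completion_frame`, `motorized_onset_frame`, `search_interval`,
#'   `motorized_interval` (frame ranges), `motorized_speed` (um/s),
#'   `onset_separation` (um), `sse`.
#' @export
segment_phases <- function(series, completion) {
  stopifnot(inherits(series, "separation_series"))
  if (is.na(completion)) stop("completion frame is required")
  frames <- series$data$frame
  ic <- match(completion, frames)
  if (is.na(ic)) stop("completion frame not in series")
  d <- series$data$d_um[seq_len(ic)]
  dt <- series$frame_interval
  rejected <- structure(list(
    segmentable = FALSE, completion_frame = completion,
    motorized_onset_frame = NA_integer_, search_interval = c(NA, NA),
    motorized_interval = c(NA, NA), motorized_speed = NA_real_,
    onset_separation = NA_real_, sse = NA_real_
  ), class = "phase_segmentation")
  if (ic < 4) return(rejected)
  d_c <- d[ic]
  cands <- 1:(ic - 2)
  sse <- numeric(length(cands))
  slope <- numeric(length(cands))
  for (q in seq_along(cands)) {
    t_star <- cands[q]
    c_hat <- mean(d[1:t_star])
    w <- (t_star:ic) - ic # <= 0
    resid_ramp <- d[t_star:ic] - d_c
    s_hat <- sum(w * resid_ramp) / sum(w^2)
    sse[q] <- sum((d[1:t_star] - c_hat)^2) +
      sum((resid_ramp - s_hat * w)^2)
    slope[q] <- s_hat
  }
  q_best <- which.min(sse) # first minimum = earliest changepoint on ties
  if (slope[q_best] >= 0) return(rejected)
  t_star <- cands[q_best]
  structure(list(
    segmentable = TRUE,
    completion_frame = completion,
    motorized_onset_frame = frames[t_star],
    search_interval = c(frames[1], frames[t_star]),
    motorized_interval = c(frames[t_star], completion),
    motorized_speed = abs(slope[q_best]) / dt,
    onset_separation = d[t_star],
    sse = sse[q_best]
  ), class = "phase_segmentation")
}

#' Mean square displacement of pair separation
#'
#' Time-averaged (lag-based) estimator by default:
#' `MSD(tau) = mean over pairs and start times t of (d(t+tau) - d(t))^2`,
#' with both end points restricted to the requested phase window. The
#' `"origin"` estimator instead measures displacement from the first frame
#' of the phase window. Lags with no valid sample pairs are omitted;
#' lag 0 is identically 0.
#'
#' @param series_list a `separation_series` or list of them.
#' @param phase `"all"` or `"search"`; `"search"` restricts each series to
#'   its search-and-capture interval (from `segmentations`, or the whole
#'   pre-anaphase span for pairs without one).
#' @param max_lag_s maximum lag (s); default half the longest series.
#' @param estimator `"lag"` (time-averaged) or `"origin"`.
#' @param segmentations optional list of [segment_phases()] results
#'   parallel to `series_list` (used when `phase = "search"`).
#' @return A data.frame of class `msd_curve`: `lag_s`, `msd_um2`, `n`.
#' @export
msd <- function(series_list, phase = c("all", "search"), max_lag_s = NULL,
                estimator = c("lag", "origin"), segmentations = NULL) {
  phase <- match.arg(phase)
  estimator <- match.arg(estimator)
  if (inherits(series_list, "separation_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("at least one series is required")
  windows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    d <- s$data$d_um
    idx <- seq_along(d)
    if (phase == "search") {
      seg <- if (!is.null(segmentations)) segmentations[[i]] else NULL
      if (!is.null(seg) && isTRUE(seg$segmentable)) {
        idx <- idx[s$data$frame <= seg$motorized_onset_frame]
      } else if (!is.na(s$anaphase_onset_frame)) {
        idx <- idx[s$data$frame <= s$anaphase_onset_frame]
      }
    }
    list(d = d[idx], dt = s$frame_interval)
  })
  dt <- windows[[1]]$dt
  max_len <- max(vapply(windows, function(w) length(w$d), integer(1)))
  max_lag <- if (is.null(max_lag_s)) floor(max_len / 2) else floor(max_lag_s / dt)
  lags <- 0:max_lag
  msd_v <- numeric(length(lags)); n_v <- integer(length(lags))
  msd_v[1] <- 0
  n_v[1] <- sum(vapply(windows, function(w) length(w$d), integer(1)))
  for (li in seq_along(lags)[-1]) {
    k <- lags[li]
    sq <- unlist(lapply(windows, function(w) {
      m <- length(w$d)
      if (estimator == "lag") {
        if (m <= k) return(numeric(0))
        (w$d[(1 + k):m] - w$d[1:(m - k)])^2
      } else {
        if (m <= k) return(numeric(0))
        (w$d[1 + k] - w$d[1])^2
      }
    }))
    msd_v[li] <- if (length(sq)) mean(sq) else NA_real_
    n_v[li] <- length(sq)
  }
  keep <- n_v > 0 | lags == 0
  structure(data.frame(lag_s = lags[keep] * dt, msd_um2 = msd_v[keep],
                       n = n_v[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Population mean and SD of separation aligned at an event
#'
#' Aligns every series at the chosen event (aligned time 0) and reports the
#' cross-pair mean, SD and contributing n of d at each aligned time point.
#' SD is `NA` where fewer than 2 series contribute; series lacking the
#' event are excluded with a warning.
#'
#' @param series_list list of [separation_series()].
#' @param event `"completion"` or `"anaphase_onset"`.
#' @param completions completion frames parallel to `series_list`
#'   (required for `event = "completion"`).
#' @return A data.frame: `aligned_time_s`, `mean_d`, `sd_d`, `n`.
#' @export
align_population <- function(series_list, event = c("completion", "anaphase_onset"),
                             completions = NULL) {
  event <- match.arg(event)
  if (inherits(series_list, "separation_series")) series_list <- list(series_list)
  events <- vapply(seq_along(series_list), function(i) {
    if (event == "completion") {
      if (is.null(completions)) NA_integer_ else as.integer(completions[[i]])
    } else {
      as.integer(series_list[[i]]$anaphase_onset_frame)
    }
  }, integer(1))
  keep <- !is.na(events)
  if (any(!keep)) warning(sprintf("%d series lack the alignment event and were excluded",
                                  sum(!keep)))
  series_list <- series_list[keep]; events <- events[keep]
  if (!length(series_list)) stop("no series carry the alignment event")
  rows <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(at = s$data$frame - events[i], d = s$data$d_um,
               dt = s$frame_interval)
  }))
  ag <- do.call(rbind, lapply(split(rows, rows$at), function(g) {
    data.frame(aligned_time_s = g$at[1] * g$dt[1], mean_d = mean(g$d),
               sd_d = if (nrow(g) >= 2) stats::sd(g$d) else NA_real_,
               n = nrow(g))
  }))
  ag <- ag[order(ag$aligned_time_s), ]
  rownames(ag) <- NULL
  ag
}

#' Classify pairs as clustered or failed
#'
#' A pair is clustered iff [detect_completion()] finds a completion frame.
#' The summary reports counts and, where anaphase annotations exist, the
#' fraction of clustered pairs completing at or before anaphase onset.
#'
#' @param series_list list of [separation_series()].
#' @inheritParams detect_completion
#' @return A list: `table` (data.frame `pair_id`, `clustered`,
#'   `completion_frame`) and `summary` (list `n_clustered`, `n_failed`,
#'   `fraction_clustered`, `fraction_before_anaphase`).
#' @export
classify_pairs <- function(series_list, d_clustered = 2, stability_window = 5,
                           stability_sd = 0.3) {
  if (inherits(series_list, "separation_series")) series_list <- list(series_list)
  tab <- do.call(rbind, lapply(series_list, function(s) {
    comp <- detect_completion(s, d_clustered, stability_window, stability_sd)
    data.frame(pair_id = s$pair_id, clustered = !is.na(comp),
               completion_frame = comp,
               anaphase_onset_frame = s$anaphase_onset_frame)
  }))
  before <- with(tab, clustered & !is.na(anaphase_onset_frame) &
                   completion_frame <= anaphase_onset_frame)
  n_annot <- sum(tab$clustered & !is.na(tab$anaphase_onset_frame))
  list(table = tab[, c("pair_id", "clustered", "completion_frame")],
       summary = list(
         n_clustered = sum(tab$clustered),
         n_failed = sum(!tab$clustered),
         fraction_clustered = mean(tab$clustered),
         fraction_before_anaphase = if (n_annot) sum(before) / n_annot else NA_real_))
}

#' Pooled histogram of separation during the search-and-capture phase
#'
#' Pools d samples over the search-and-capture phase of clustered pairs
#' (frames up to the motorized onset from their segmentation) and the whole
#' pre-anaphase span of failed pairs, bins them in right-open bins of
#' `bin_width` from 0, and reports the pooled median with a bootstrap SEM.
#'
#' @param series_list list of [separation_series()].
#' @param segmentations list parallel to `series_list`: a
#'   [segment_phases()] result for clustered pairs, `NULL` for failed ones.
#' @param bin_width histogram bin width (um).
#' @param n_boot bootstrap resamples for the SEM of the median.
#' @param boot_seed seed for the bootstrap.
#' @return A list of class `phase_histogram`: `breaks`, `counts`, `mids`,
#'   `median`, `sem_median`, `n`.
#' @export
phase_histogram <- function(series_list, segmentations = NULL, bin_width = 1,
                            n_boot = 1000, boot_seed = 1L) {
  if (inherits(series_list, "separation_series")) series_list <- list(series_list)
  pooled <- unlist(lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    seg <- if (!is.null(segmentations)) segmentations[[i]] else NULL
    if (!is.null(seg) && isTRUE(seg$segmentable)) {
      s$data$d_um[s$data$frame <= seg$motorized_onset_frame]
    } else if (!is.na(s$anaphase_onset_frame)) {
      s$data$d_um[s$data$frame <= s$anaphase_onset_frame]
    } else {
      s$data$d_um
    }
  }))
  if (!length(pooled)) stop("no separation samples to pool")
  breaks <- seq(0, (max(pooled) %/% bin_width + 1) * bin_width, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, right = FALSE, plot = FALSE)
  .set_seed(boot_seed)
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(pooled, replace = TRUE)), numeric(1))
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 median = stats::median(pooled),
                 sem_median = stats::sd(meds), n = length(pooled)),
            class = "phase_histogram")
}
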