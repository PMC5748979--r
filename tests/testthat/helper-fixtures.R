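# shared fixtures and independent oracles, built in code at test time

# wrap a separation vector as a separation_series
make_series <- function(d, frame_interval = 40, anaphase = NA_integer_,
                        pair_id = "p") {
  structure(list(
    data = data.frame(frame = seq_along(d),
                      time_s = (seq_along(d) - 1) * frame_interval,
                      d_um = d, interpolated = FALSE),
    pair_id = pair_id, condition_label = NA_character_,
    anaphase_onset_frame = as.integer(anaphase),
    frame_interval = frame_interval
  ), class = "separation_series")
}

# noiseless two-piece series: plateau of `v` frames at `plateau`, then a
# linear descent to `final` over the remaining frames; the vertex (frame v)
# carries the plateau value and lies on the descent line
two_piece <- function(len, vertex, plateau = 10, final = 1) {
  ramp <- plateau + (final - plateau) * seq_len(len - vertex) / (len - vertex)
  c(rep(plateau, vertex), ramp)
}

# brute-force changepoint oracle: naive loops over every candidate,
# plateau mean + least-squares line through the completion anchor
brute_changepoint <- function(d) {
  ic <- length(d)
  d_c <- d[ic]
  best_sse <- Inf
  best_t <- NA_integer_
  for (t_star in 1:(ic - 2)) {
    c_hat <- mean(d[1:t_star])
    sse <- 0
    for (t in 1:t_star) sse <- sse + (d[t] - c_hat)^2
    num <- 0; den <- 0
    for (t in t_star:ic) {
      w <- t - ic
      num <- num + w * (d[t] - d_c)
      den <- den + w^2
    }
    s_hat <- num / den
    for (t in t_star:ic) sse <- sse + (d[t] - d_c - s_hat * (t - ic))^2
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_t <- t_star
    }
  }
  best_t
}

# analytic single-spot stack (independent of render_stack)
gauss_stack <- function(center, n_x = 21, n_y = 21, n_z = 11,
                        pixel = 0.13, z_sp = 0.5, amplitude = 500,
                        background = 10, sxy = 0.11, sz = 0.35,
                        frame_interval = 40, n_frames = 1) {
  xc <- (seq_len(n_x) - 0.5) * pixel
  yc <- (seq_len(n_y) - 0.5) * pixel
  zc <- (seq_len(n_z) - 0.5) * z_sp
  one <- background + amplitude *
    outer(exp(-(zc - center[3])^2 / (2 * sz^2)),
          outer(exp(-(yc - center[2])^2 / (2 * sxy^2)),
                exp(-(xc - center[1])^2 / (2 * sxy^2))))
  data <- array(0, dim = c(n_frames, n_z, n_y, n_x))
  for (t in seq_len(n_frames)) data[t, , , ] <- one
  image_stack(data, pixel, z_sp, frame_interval)
}

# match each trajectory to a truth centrosome per frame; returns the RMSE
# of the best consistent assignment and the number of identity swaps
# (frames where the nearest truth centrosome differs from the majority one)
match_to_truth <- function(trajs, truth) {
  stats <- lapply(trajs, function(td) {
    obs <- as.matrix(td[, c("x_um", "y_um", "z_um")])
    nearest <- vapply(seq_len(nrow(td)), function(i) {
      dists <- vapply(1:2, function(s)
        sqrt(sum((obs[i, ] - truth$positions[td$frame[i], , s])^2)), numeric(1))
      which.min(dists)
    }, integer(1))
    major <- as.integer(names(sort(table(nearest), decreasing = TRUE))[1])
    err2 <- vapply(seq_len(nrow(td)), function(i)
      sum((obs[i, ] - truth$positions[td$frame[i], , major])^2), numeric(1))
    list(swaps = sum(nearest != major), sse = sum(err2), n = nrow(td))
  })
  list(rmse = sqrt(sum(vapply(stats, `[[`, numeric(1), "sse")) /
                     sum(vapply(stats, `[[`, numeric(1), "n"))),
       swaps = sum(vapply(stats, `[[`, numeric(1), "swaps")))
}
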