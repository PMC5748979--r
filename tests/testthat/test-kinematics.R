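static_traj <- function(xyz, n = 5) {
  data.frame(frame = 1:n, time_s = (0:(n - 1)) * 40,
             x_um = xyz[1], y_um = xyz[2], z_um = xyz[3])
}

test_that("separation series is the Euclidean distance on common frames", {
  a <- static_traj(c(0, 0, 0)); b <- static_traj(c(3, 4, 0))
  s <- separation_series(a, b)
  expect_equal(s$data$d_um, rep(5, 5))
  expect_equal(separation_series(a, a)$data$d_um, rep(0, 5))
  # symmetric in its arguments
  expect_equal(separation_series(a, b)$data$d_um,
               separation_series(b, a)$data$d_um)
  # requires at least 3 common frames
  expect_error(separation_series(a[1:2, ], b), "3 common frames")
})

test_that("completion is the earliest stably-low frame", {
  # step function: 10 for frames 1-10, then 1.5
  s <- make_series(c(rep(10, 10), rep(1.5, 10)))
  expect_identical(detect_completion(s), 11L)
  # monotone decrease that never reaches the threshold: none
  s2 <- make_series(seq(12, 3, length.out = 30))
  expect_true(is.na(detect_completion(s2)))
  # shorter than the stability window: none, with a warning
  expect_warning(res <- detect_completion(make_series(c(1, 1, 1))), "window")
  expect_true(is.na(res))
})

test_that("completion detection is monotone in the distance threshold", {
  set.seed(7)
  for (rep in 1:10) {
    d <- c(10 - cumsum(runif(20, 0, 0.6)), rep(1.5, 15) + rnorm(15, 0, 0.05))
    d <- pmax(d, 0.5)
    s <- make_series(d)
    comps <- vapply(c(1.8, 2, 2.5, 3), function(thr)
      as.numeric(detect_completion(s, d_clustered = thr)), numeric(1))
    comps <- comps[!is.na(comps)]
    if (length(comps) > 1) expect_true(all(diff(comps) <= 0))
  }
})

test_that("completion and phase segmentation recover simulated truth", {
  # noiseless descent pair
  tr <- simulate_pair(motion_params(sd_search = 0, mean_separation_search = 7.5,
                                    onset_separation = 7.5, n_frames = 40,
                                    seed = 1))
  s <- truth_separation(tr)
  expect_identical(detect_completion(s), tr$completion_frame)
  seg <- segment_phases(s, tr$completion_frame)
  expect_identical(seg$motorized_onset_frame, tr$motorized_onset_frame)
  expect_equal(seg$onset_separation, 7.5)
})

test_that("the changepoint fit matches the worked two-piece example", {
  # plateau 10 um for 20 frames (vertex frame 21), descent to 1 um over 23
  d <- two_piece(44, 21, plateau = 10, final = 1)
  s <- make_series(d)
  seg <- segment_phases(s, 44L)
  expect_true(seg$segmentable)
  expect_identical(seg$motorized_onset_frame, 21L)
  expect_equal(seg$motorized_speed, 9 / (23 * 40), tolerance = 1e-12)
  expect_equal(seg$onset_separation, 10)
  expect_identical(seg$motorized_interval, c(21L, 44L))
  # a pure plateau has no negative descent slope: rejected
  flat <- make_series(rep(5, 30))
  expect_false(segment_phases(flat, 30L)$segmentable)
})

test_that("changepoint recovery agrees with the brute-force SSE oracle", {
  for (L in c(12, 25, 41)) {
    for (v in seq(1, L - 3, by = 3)) {
      d <- two_piece(L, v)
      seg <- segment_phases(make_series(d), L)
      expect_identical(seg$motorized_onset_frame, as.integer(v))
      expect_identical(brute_changepoint(d), as.integer(v))
    }
  }
})

test_that("MSD obeys its closed forms", {
  expect_true(all(msd(make_series(rep(5, 40)))$msd_um2 == 0))
  cc <- 0.005
  m <- msd(make_series(cc * 40 * (0:39)))
  expect_equal(m$msd_um2, (cc * m$lag_s)^2, tolerance = 1e-10)
  # invariant to adding a constant to d
  set.seed(2)
  d <- cumsum(rnorm(50, 0, 0.3)) + 10
  expect_equal(msd(make_series(d))$msd_um2, msd(make_series(d + 7))$msd_um2)
  # lag 0 is identically 0 and reported
  expect_equal(m$msd_um2[m$lag_s == 0], 0)
})

test_that("aligned population statistics match direct recomputation", {
  s1 <- make_series(rep(10, 20), anaphase = 15)
  s2 <- make_series(rep(12, 20), anaphase = 15)
  ap <- align_population(list(s1, s2), "anaphase_onset")
  expect_equal(unique(ap$mean_d), 11)
  expect_equal(unique(ap$sd_d), sqrt(2), tolerance = 1e-12)
  expect_equal(ap$aligned_time_s, ((1:20) - 15) * 40)
  # single series: SD not reported
  ap1 <- align_population(list(s1), "anaphase_onset")
  expect_true(all(is.na(ap1$sd_d)))
  # brute-force check on ragged random input
  set.seed(4)
  sers <- lapply(1:5, function(i)
    make_series(rnorm(10 + i, 10), anaphase = 5 + i))
  ap2 <- align_population(sers, "anaphase_onset")
  for (r in sample(nrow(ap2), 5)) {
    at <- ap2$aligned_time_s[r] / 40
    vals <- unlist(lapply(sers, function(s) {
      j <- which(s$data$frame - s$anaphase_onset_frame == at)
      s$data$d_um[j]
    }))
    expect_equal(ap2$mean_d[r], mean(vals))
    expect_equal(ap2$n[r], length(vals))
    if (length(vals) >= 2) expect_equal(ap2$sd_d[r], sd(vals))
  }
  # series without the event are excluded with a warning
  s3 <- make_series(rep(9, 20))
  expect_warning(align_population(list(s1, s2, s3), "anaphase_onset"),
                 "excluded")
})

test_that("pairs classify by completion detection with zero confusion on truth", {
  low <- make_series(rep(1.5, 20))
  high <- make_series(rep(11, 20))
  cls <- classify_pairs(list(low, high))
  expect_identical(cls$table$clustered, c(TRUE, FALSE))
  expect_identical(cls$table$completion_frame[1], 1L)
  # mixed simulated ensemble, truth-labelled
  sers <- c(
    lapply(1:15, function(i) truth_separation(
      simulate_pair(motion_params(cluster = TRUE, n_frames = 70, seed = 400 + i)),
      pair_id = paste0("c", i))),
    lapply(1:15, function(i) truth_separation(
      simulate_pair(motion_params(cluster = FALSE, seed = 500 + i)),
      pair_id = paste0("f", i))))
  truth_flag <- rep(c(TRUE, FALSE), each = 15)
  cls2 <- classify_pairs(sers)
  expect_identical(cls2$table$clustered, truth_flag)
  expect_equal(cls2$summary$n_clustered, 15)
  # clustering completes before anaphase onset in the generator's truth
  expect_equal(cls2$summary$fraction_before_anaphase, 1)
})

test_that("search-phase histogram pools, conserves counts and reports a median", {
  s <- make_series(rep(7.5, 30))
  h <- phase_histogram(list(s))
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$median, 7.5)
  expect_equal(sum(h$counts), h$n)
  # non-clustering ensemble pools near the generator's search baseline
  sers <- lapply(1:30, function(i) truth_separation(
    simulate_pair(motion_params(cluster = FALSE, seed = 600 + i))))
  h2 <- phase_histogram(sers)
  expect_gt(h2$median, 11)
  expect_lt(h2$median, 12)
  expect_equal(sum(h2$counts), h2$n)
  expect_gt(h2$sem_median, 0)
})

test_that("aligned-population SD scales with the generator's search SD", {
  pooled_sd <- function(sd_um, n, seed0) {
    sers <- lapply(seq_len(n), function(i) truth_separation(
      simulate_pair(motion_params(cluster = FALSE, sd_search = sd_um,
                                  seed = seed0 + i))))
    ap <- align_population(sers, "anaphase_onset")
    sqrt(mean(ap$sd_d[ap$n == n]^2))
  }
  ratio <- pooled_sd(2, 25, 700) / pooled_sd(1, 25, 800)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})
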