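test_that("noiseless pair at the onset distance descends linearly over ceil(duration/dt) intervals", {
  mp <- motion_params(cluster = TRUE, sd_search = 0, mean_separation_search = 7.5,
                      onset_separation = 7.5, motorized_duration = 900,
                      frame_interval = 40, n_frames = 40, seed = 1)
  tr <- simulate_pair(mp)
  n_steps <- ceiling(900 / 40)
  expect_identical(tr$motorized_onset_frame, 1L)
  expect_identical(tr$completion_frame, as.integer(1 + n_steps))
  # linear descent from 7.5 to the plateau
  k <- 0:n_steps
  expect_equal(tr$separation[1 + k], 7.5 + (1.8 - 7.5) * k / n_steps,
               tolerance = 1e-12)
  # post-completion fluctuation stays within 0.1 um of the plateau (SD contract)
  post <- tr$separation[(1 + n_steps + 1):40]
  expect_lt(sd(post), 0.1)
})

test_that("same seed gives bit-identical output; different seeds differ", {
  a <- simulate_pair(motion_params(seed = 42))
  b <- simulate_pair(motion_params(seed = 42))
  c <- simulate_pair(motion_params(seed = 43))
  expect_identical(a, b)
  expect_false(identical(a$separation, c$separation))
})

test_that("separation equals the recomputed pairwise distance at every frame", {
  for (seed in 1:5) {
    tr <- simulate_pair(motion_params(cluster = seed %% 2 == 0, seed = seed))
    d <- sqrt(rowSums((tr$positions[, , 1] - tr$positions[, , 2])^2))
    expect_lt(max(abs(d - tr$separation)), 1e-9)
  }
})

test_that("non-clustering pairs report no motorized onset or completion and are stationary", {
  mp <- motion_params(cluster = FALSE, sd_search = 1, n_frames = 400, seed = 9)
  tr <- simulate_pair(mp)
  expect_true(is.na(tr$motorized_onset_frame))
  expect_true(is.na(tr$completion_frame))
  # long-run temporal SD near the stationary SD of the process
  expect_gt(sd(tr$separation), 0.6)
  expect_lt(sd(tr$separation), 1.4)
})

test_that("motion parameter invariants are enforced", {
  expect_error(motion_params(final_separation = 8, onset_separation = 7.5),
               "final_separation")
  expect_error(motion_params(onset_separation = 12, mean_separation_search = 11.5),
               "onset_separation")
  expect_error(motion_params(sd_search = -1))
  expect_error(motion_params(n_frames = 0))
})

test_that("noiseless render puts the intensity maximum at the true position", {
  mp <- motion_params(cluster = FALSE, sd_search = 0, mean_separation_search = 8,
                      onset_separation = 7.5, n_frames = 2, seed = 1)
  tr <- simulate_pair(mp, midpoint = c(6, 6, 4.25))
  op <- optics_params(noise_model = "none", n_z = 17)
  st <- render_stack(tr, op, volume_xy_um = c(12, 12))
  fr <- st$data[1, , , ]
  amax <- which(fr == max(fr), arr.ind = TRUE)[1, ] # z, y, x
  p <- tr$positions[1, , 1]
  q <- tr$positions[1, , 2]
  vox_of <- function(pos) c(ceiling(pos[3] / 0.5), ceiling(pos[2] / 0.13),
                            ceiling(pos[1] / 0.13))
  expect_true(all(amax == vox_of(p)) || all(amax == vox_of(q)))
})

test_that("two well-separated noiseless spots give two disjoint half-max components", {
  mp <- motion_params(cluster = FALSE, sd_search = 0, mean_separation_search = 10,
                      onset_separation = 7.5, n_frames = 1, seed = 2)
  tr <- simulate_pair(mp, midpoint = c(7, 7, 8.75))
  op <- optics_params(noise_model = "none", background = 0)
  st <- render_stack(tr, op, volume_xy_um = c(14, 14))
  proj <- project_frame(st, 1)
  above <- proj > max(proj) / 2
  # the two above-half-max regions sit at the spots' projected positions,
  # far apart relative to the PSF
  idx <- which(above, arr.ind = TRUE)
  dists <- as.matrix(dist(idx)) * 0.13
  xy_sep <- sqrt(sum((tr$positions[1, 1:2, 1] - tr$positions[1, 1:2, 2])^2))
  expect_gt(xy_sep, 2) # well separated in projection for this seed
  expect_equal(max(dists), xy_sep, tolerance = 0.15)
  # each region spans only a few PSF-sized pixels: two disjoint components
  expect_lt(sum(above), 2 * 25)
  expect_gt(sum(dists > xy_sep / 2), 2) # pixels split into two distant groups
})

test_that("rendering a position outside the volume names the frame and centrosome", {
  mp <- motion_params(cluster = FALSE, sd_search = 0, mean_separation_search = 10,
                      onset_separation = 7.5, n_frames = 1, seed = 1)
  tr <- simulate_pair(mp, midpoint = c(2, 2, 4.25))
  op <- optics_params(noise_model = "none", n_z = 17)
  expect_error(render_stack(tr, op, volume_xy_um = c(5, 5)),
               "frame 1, centrosome")
})

test_that("Poisson renders are unbiased at the spot centre", {
  mp <- motion_params(cluster = FALSE, sd_search = 0, mean_separation_search = 8,
                      onset_separation = 7.5, n_frames = 1, seed = 3)
  tr <- simulate_pair(mp, midpoint = c(5, 5, 2.75))
  clean <- render_stack(tr, optics_params(noise_model = "none", n_z = 11),
                        volume_xy_um = c(10, 10))
  p <- tr$positions[1, , 1]
  vz <- ceiling(p[3] / 0.5); vy <- ceiling(p[2] / 0.13); vx <- ceiling(p[1] / 0.13)
  mu <- clean$data[1, vz, vy, vx]
  vals <- vapply(1:100, function(i) {
    st <- render_stack(tr, optics_params(noise_model = "poisson", n_z = 11,
                                         seed = 1000 + i),
                       volume_xy_um = c(10, 10))
    st$data[1, vz, vy, vx]
  }, numeric(1))
  se <- sqrt(mu / 100) # Poisson SE of the mean
  expect_lt(abs(mean(vals) - mu), 3 * se)
})

test_that("tripolar construction realizes the requested smallest angle exactly", {
  eq <- simulate_tripolar(3, angle_mean = 120, angle_sd = 0, seed = 1)
  for (s in eq) expect_equal(pole_angles(s), rep(120, 3), tolerance = 1e-9)
  sp <- simulate_tripolar(5, angle_mean = 60, angle_sd = 0, seed = 2)
  for (s in sp) expect_equal(smallest_pole_angle(s), 60, tolerance = 1e-9)
  expect_error(simulate_tripolar(3, angle_mean = 130), "120")
})

test_that("tripolar population mean is recovered from 500 draws", {
  sp <- simulate_tripolar(500, angle_mean = 80, angle_sd = 15, seed = 7)
  measured <- vapply(sp, smallest_pole_angle, numeric(1))
  truth <- vapply(sp, `[[`, numeric(1), "truth_angle")
  expect_equal(measured, truth, tolerance = 1e-9)
  expect_lt(abs(mean(measured) - 80), 2)
})

test_that("noiseless force curves follow the conical Sneddon law exactly", {
  p <- afm_sim_params(true_modulus = 1000, poisson_ratio = 0.5,
                      tip_half_angle = 35, noise_sd = 0, seed = 1)
  cv <- simulate_force_curve(p)
  pre <- cv$piezo_z_um < p$contact_point
  expect_true(all(cv$deflection[pre] == 0))
  post <- cv$piezo_z_um > p$contact_point
  delta <- (cv$piezo_z_um[post] - p$contact_point) * 1000 - cv$deflection[post]
  f <- cv$spring_constant * cv$deflection[post] * 1000 # pN
  # direct closed-form evaluation, written out independently
  f_expect <- (2 / pi) * (1000 / (1 - 0.5^2)) * tan(35 * pi / 180) *
    (delta * 1e-9)^2 * 1e12
  expect_equal(f, f_expect, tolerance = 1e-9)
  # spot value at delta = 500 nm
  expect_equal(sneddon_force(500, 1000, 0.5, 35),
               (2 / pi) * (1000 / 0.75) * tan(35 * pi / 180) * (500e-9)^2 * 1e12)
})

test_that("force-curve simulation is deterministic per seed", {
  a <- simulate_force_curve(afm_sim_params(seed = 5))
  b <- simulate_force_curve(afm_sim_params(seed = 5))
  expect_identical(a$deflection, b$deflection)
})
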