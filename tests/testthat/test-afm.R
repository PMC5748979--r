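test_that("glass-curve sensitivity is the inverse post-contact slope", {
  z <- seq(0, 3, by = 0.005)
  # ideal rigid contact in matched units: deflection (nm) = z - z0 beyond z0
  ideal <- force_curve(z, pmax(z - 1.5, 0) * 1000, spring_constant = 0.006)
  expect_equal(sensitivity_from_glass(ideal), 1, tolerance = 1e-9)
  # deflection recorded in volts with a known 50 nm/V lever sensitivity
  volts <- force_curve(z, pmax(z - 1.5, 0) * 1000 / 50, spring_constant = 0.006,
                       deflection_unit = "V")
  expect_equal(sensitivity_from_glass(volts), 50, tolerance = 0.5)
  # pre-contact-only curve: no linear region
  flat <- force_curve(z, rep(0, length(z)), spring_constant = 0.006)
  expect_error(sensitivity_from_glass(flat), "linear region")
})

test_that("contact point is recovered within one sample spacing (noiseless)", {
  cv <- simulate_force_curve(afm_sim_params(noise_sd = 0, contact_point = 2,
                                            seed = 1))
  z0 <- find_contact_point(cv)
  expect_lt(abs(z0 - 2), 0.005) # one 5 nm spacing
  # pure-noise curve: no contact
  set.seed(2)
  noise <- force_curve(seq(0, 3, by = 0.005),
                       rnorm(601, 0, 3), spring_constant = 0.006)
  expect_error(find_contact_point(noise), "no contact")
})

test_that("contact-point recovery is unbiased under 20 pN noise", {
  zs <- vapply(1:100, function(i) {
    cv <- simulate_force_curve(afm_sim_params(noise_sd = 20, seed = 3000 + i))
    find_contact_point(cv)
  }, numeric(1))
  expect_lt(abs(mean(zs) - 2) * 1000, 2 * 5) # bias under two sample spacings
})

test_that("indentation follows delta = (z - z0) - d with F = k d", {
  z <- seq(0, 3, by = 0.01)
  # rigid substrate: deflection = piezo travel, so delta is identically 0
  rigid <- force_curve(z, pmax(z - 1, 0) * 1000, spring_constant = 0.006)
  di <- indentation_force(rigid, 1)
  expect_true(all(abs(di$delta_nm) < 1e-9))
  # zero deflection: delta = z - z0 and F = 0
  free <- force_curve(z, rep(0, length(z)), spring_constant = 0.006)
  di2 <- indentation_force(free, 1)
  expect_equal(di2$delta_nm, (z[z > 1] - 1) * 1000)
  expect_true(all(di2$force_pN == 0))
  # volts without sensitivity cannot be interpreted
  v <- force_curve(z, rep(0.1, length(z)), spring_constant = 0.006,
                   deflection_unit = "V")
  expect_error(indentation_force(v, 1), "sensitivity")
  expect_error(indentation_force(free, 5), "range")
  # simulated soft-sample curve reproduces the generating Sneddon law
  p <- afm_sim_params(true_modulus = 600, noise_sd = 0, seed = 4)
  cv <- simulate_force_curve(p)
  di3 <- indentation_force(cv, p$contact_point)
  expect_equal(di3$force_pN,
               sneddon_force(di3$delta_nm, 600, p$poisson_ratio,
                             p$tip_half_angle),
               tolerance = 1e-6)
})

test_that("position averaging is pointwise and reduces noise like sqrt(n)", {
  grid <- data.frame(delta_nm = seq(10, 900, by = 5))
  f <- sneddon_force(grid$delta_nm, 500)
  one <- data.frame(delta_nm = grid$delta_nm, force_pN = f)
  avg_same <- average_position_curves(list(one, one, one))
  expect_equal(avg_same$force_pN,
               approx(one$delta_nm, one$force_pN, avg_same$delta_nm)$y,
               tolerance = 1e-9)
  three <- data.frame(delta_nm = grid$delta_nm, force_pN = 3 * f)
  avg2 <- average_position_curves(list(one, three))
  expect_equal(avg2$force_pN,
               2 * approx(one$delta_nm, one$force_pN, avg2$delta_nm)$y,
               tolerance = 1e-9)
  expect_error(average_position_curves(list(
    one, data.frame(delta_nm = 2000 + grid$delta_nm, force_pN = f))),
    "disjoint")
  # noise averaging: residual SD about the true curve shrinks ~ sqrt(10)
  set.seed(5)
  noisy <- lapply(1:10, function(i)
    data.frame(delta_nm = grid$delta_nm, force_pN = f + rnorm(length(f), 0, 20)))
  avg10 <- average_position_curves(noisy)
  f_true <- sneddon_force(avg10$delta_nm, 500)
  ratio <- 20 / sd(avg10$force_pN - f_true)
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.4)
})

test_that("the Sneddon fit inverts the forward model and respects the depth cap", {
  delta <- seq(5, 1500, by = 5)
  df <- data.frame(delta_nm = delta,
                   force_pN = sneddon_force(delta, 1000, 0.5, 35))
  est <- fit_sneddon(df, max_depth = 800, tip_half_angle = 35,
                     poisson_ratio = 0.5)
  expect_lt(abs(est$apparent_modulus - 1000) / 1000, 0.01)
  expect_lte(est$depth_used, 800)
  # doubling all forces doubles the fitted modulus exactly
  df2 <- df; df2$force_pN <- 2 * df$force_pN
  est2 <- fit_sneddon(df2)
  expect_equal(est2$apparent_modulus, 2 * est$apparent_modulus,
               tolerance = 1e-12)
  # samples beyond 800 nm are excluded: corrupting them changes nothing
  df3 <- df; df3$force_pN[df3$delta_nm > 800] <- 1e6
  expect_equal(fit_sneddon(df3)$apparent_modulus, est$apparent_modulus,
               tolerance = 1e-12)
  expect_error(fit_sneddon(df[1:5, ]), "10 samples")
  neg <- data.frame(delta_nm = delta[1:50], force_pN = -df$force_pN[1:50])
  expect_error(fit_sneddon(neg), "non-positive")
})

test_that("the fitted modulus is invariant to recording deflection in volts", {
  p <- afm_sim_params(true_modulus = 900, noise_sd = 0, seed = 6)
  cv <- simulate_force_curve(p)
  sens <- 40 # nm/V
  cv_v <- force_curve(cv$piezo_z_um, cv$deflection / sens,
                      spring_constant = cv$spring_constant,
                      deflection_unit = "V", sensitivity = sens)
  z0 <- find_contact_point(cv)
  z0v <- find_contact_point(cv_v)
  expect_equal(z0v, z0, tolerance = 1e-9)
  e1 <- fit_sneddon(indentation_force(cv, z0))$apparent_modulus
  e2 <- fit_sneddon(indentation_force(cv_v, z0v))$apparent_modulus
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("residuals are self-consistent with the fitted model", {
  delta <- seq(5, 900, by = 5)
  set.seed(7)
  df <- data.frame(delta_nm = delta,
                   force_pN = sneddon_force(delta, 700) + rnorm(length(delta), 0, 15))
  est <- fit_sneddon(df)
  beta <- est$apparent_modulus * 2 * tan(35 * pi / 180) / (pi * (1 - 0.25)) / 1e6
  sel <- df$delta_nm <= 800
  resid <- df$force_pN[sel] - beta * df$delta_nm[sel]^2
  expect_equal(est$fit_rms, sqrt(mean(resid^2)), tolerance = 1e-9)
})

test_that("per-cell summaries aggregate position moduli", {
  ests <- lapply(1:4, function(i)
    structure(list(position_id = paste0("p", i), cell_id = "c1",
                   apparent_modulus = 500), class = "elasticity_estimate"))
  ce <- cell_elasticity(ests)
  expect_equal(ce$mean_modulus, 500)
  expect_equal(ce$sd_modulus, 0)
  expect_equal(ce$n_positions, 4L)
  df <- data.frame(cell_id = "c2", apparent_modulus = c(400, 600))
  ce2 <- cell_elasticity(df)
  expect_equal(ce2$mean_modulus, 500)
  expect_equal(ce2$sd_modulus, sd(c(400, 600)), tolerance = 1e-12)
  # end-to-end: 4 positions x 5 noisy curves recover the true modulus
  ests3 <- lapply(1:4, function(pi) {
    curves <- lapply(1:5, function(ri) {
      cv <- simulate_force_curve(
        afm_sim_params(true_modulus = 800, noise_sd = 20,
                       seed = 4000 + pi * 10 + ri),
        position_id = paste0("p", pi))
      indentation_force(cv, find_contact_point(cv))
    })
    est <- fit_sneddon(average_position_curves(curves),
                       position_id = paste0("p", pi))
    est$cell_id <- "c3"
    est
  })
  ce3 <- cell_elasticity(ests3)
  expect_lt(abs(ce3$mean_modulus - 800) / 800, 0.1)
})

test_that("force curves round-trip through TSV with metadata", {
  cv <- simulate_force_curve(afm_sim_params(seed = 8), position_id = "pX",
                             cell_id = "cY")
  path <- file.path(tempdir(), "curve.tsv")
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$piezo_z_um, cv$piezo_z_um, tolerance = 1e-9)
  expect_equal(back$deflection, cv$deflection, tolerance = 1e-9)
  expect_equal(back$spring_constant, cv$spring_constant)
  expect_identical(back$position_id, "pX")
  unlink(c(path, paste0(path, ".json")))
})
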