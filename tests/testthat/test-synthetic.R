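test_that("noise-free configuration produces identical strides", {
  g <- generate_gait(gait_gen_config(latent_rank = 2, n_strides = 20,
                                     latent_amp_sd = 0, cycle_noise_sd = 0,
                                     sensor_noise_sd = 0,
                                     stride_duration_cv = 0, seed = 1))
  cyc <- segment_cycles(g$trial, g$contacts)
  for (i in seq_along(cyc)) expect_equal(cyc[[i]], cyc[[1]])
  cs <- time_normalize(cyc)
  expect_equal(gait_sd(cs)$gait_sd, 0, tolerance = 1e-12)
})

test_that("generator is a pure function of its configuration", {
  cfg <- gait_gen_config(n_strides = 15, seed = 99)
  g1 <- generate_gait(cfg)
  g2 <- generate_gait(cfg)
  expect_identical(g1$trial$samples, g2$trial$samples)
  expect_identical(g1$contacts$events, g2$contacts$events)
  g3 <- generate_gait(gait_gen_config(n_strides = 15, seed = 100))
  expect_false(identical(g1$trial$samples, g3$trial$samples))

  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(generate_gait(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("latent rank flows through to measured dimensionality", {
  g <- generate_gait(gait_gen_config(latent_rank = 3, n_strides = 60,
                                     cycle_noise_sd = 0.3,
                                     sensor_noise_sd = 0.1, seed = 17))
  vs <- variance_spectrum(g$trial$samples)
  expect_lt(100 - vs$cumulative_percent[3], 5)  # residual noise < 5%
  expect_equal(n95(vs), 3)
  expect_equal(g$ground_truth$latent_rank, 3)
})

test_that("invalid generator configurations name the offending field", {
  expect_error(gait_gen_config(seed = 1, fs = -1), "'fs'")
  expect_error(gait_gen_config(seed = 1, latent_rank = 0), "'latent_rank'")
  expect_error(gait_gen_config(seed = 1, cycle_noise_sd = -2),
               "'cycle_noise_sd'")
  expect_error(gait_gen_config(seed = 1, chaos_mod = 0.9), "'chaos_mod'")
  expect_error(gait_gen_config(n_strides = 10), "'seed'")
})

test_that("toy clouds reproduce the variance-vs-dimensionality contrast", {
  cfg <- toy_cloud_config(n_points = 5000, cov1 = diag(2),
                          cov2 = 4 * diag(2), seed = 21)
  tc <- generate_toy_clouds(cfg)
  gv1 <- generalized_variance(tc$cloud1)$gv
  gv2 <- generalized_variance(tc$cloud2)$gv
  expect_equal(gv2 / gv1, 16, tolerance = 0.15)
  expect_equal(n95(variance_spectrum(tc$cloud1)),
               n95(variance_spectrum(tc$cloud2)))

  tc2 <- generate_toy_clouds(toy_cloud_config(
    n_points = 5000, cov1 = diag(2), cov2 = diag(c(4, 1e-4)), seed = 22))
  expect_equal(n95(variance_spectrum(tc2$cloud2)), 1)
  expect_equal(n95(variance_spectrum(tc2$cloud1)), 2)

  expect_error(toy_cloud_config(n_points = 0, seed = 1), "n_points")
  expect_error(toy_cloud_config(cov2 = matrix(c(1, 2, 2, 1), 2), seed = 1),
               "cov2")
})

test_that("benchmark signals match their defining recurrences", {
  lg <- generate_benchmark("logistic", 100,
                           params = list(x0 = 0.2, transient = 0))
  expect_equal(lg[1:3], c(0.2, 0.64, 0.9216))

  w <- generate_benchmark("white", 10000, seed = 3)
  expect_lt(abs(mean(w)), 3 / sqrt(10000))

  p <- generate_benchmark("pink", 8192, seed = 4)
  pg <- stats::spec.pgram(p, plot = FALSE, taper = 0)
  slope <- coef(lm(log(pg$spec) ~ log(pg$freq)))[[2]]
  expect_equal(slope, -1, tolerance = 0.2)

  lz1 <- generate_benchmark("lorenz", 500)
  lz2 <- generate_benchmark("lorenz", 500)
  expect_identical(lz1, lz2)
  expect_equal(length(lz1), 500L)

  expect_error(generate_benchmark("brown", 1000), "valid kinds")
  expect_error(generate_benchmark("white", 50, seed = 1), "n >= 100")
  expect_error(generate_benchmark("white", 1000), "seed")
})

test_that("sine benchmark is exact", {
  s <- generate_benchmark("sine", 120, params = list(period = 60,
                                                     amplitude = 2))
  expect_equal(s[1], 0)
  expect_equal(max(s), 2, tolerance = 1e-3)
  expect_equal(s[1:60], s[61:120], tolerance = 1e-12)
})
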