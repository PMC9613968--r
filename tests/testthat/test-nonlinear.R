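test_that("AMI delay selection finds the quarter period of a sinusoid", {
  x <- generate_benchmark("sine", 6000, params = list(period = 60))
  a <- average_mutual_information(x, max_lag = 60)
  expect_false(a$fallback_used)
  expect_true(abs(a$selected_delay - 15) <= 1)
  expect_true(all(a$ami >= -1e-12))
  expect_equal(which.max(a$ami), 1)  # lag 0 carries full information

  # exact periodicity: MI at one full period equals MI at lag 0
  expect_equal(a$ami[61], a$ami[1], tolerance = 1e-10)
})

test_that("AMI of independent noise is near zero with documented fallback", {
  w <- generate_benchmark("white", 5000, seed = 7)
  a <- average_mutual_information(w, max_lag = 50)
  expect_true(all(a$ami[-1] < 0.05))
  expect_gte(a$selected_delay, 1)
  expect_error(average_mutual_information(rep(1, 1000)), "zero-entropy")
})

test_that("AMI delay is invariant to amplitude scaling", {
  g <- generate_gait(gait_gen_config(n_strides = 40, seed = 2))
  x <- g$trial$samples[, "knee_L_sagittal"]
  d1 <- average_mutual_information(x)$selected_delay
  d2 <- average_mutual_information(5 * x)$selected_delay
  expect_identical(d1, d2)
})

test_that("GFNN separates limit cycles, strange attractors and noise", {
  # Lorenz x-coordinate: the attractor unfolds by dimension 3 (false
  # neighbours essentially gone) and never needs more; at a strict 1%
  # criterion dimension 3 is required outright
  xl <- generate_benchmark("lorenz", 15000,
                           params = list(dt = 0.01, transient = 1000))
  dl <- average_mutual_information(xl, max_lag = 100)$selected_delay
  fl <- gfnn(xl, delay = dl, max_dim = 6)
  expect_gt(fl$fnn_fraction[1], 0.5)
  expect_lt(fl$fnn_fraction[3], 0.01)
  expect_true(fl$selected_dim %in% c(2L, 3L))
  fl_strict <- gfnn(xl, delay = dl, max_dim = 6, threshold = 0.01)
  expect_equal(fl_strict$selected_dim, 3L)

  # a sinusoid embeds in the plane
  xs <- generate_benchmark("sine", 3000, params = list(period = 61.7))
  fs <- gfnn(xs, delay = 15, max_dim = 5)
  expect_lte(fs$selected_dim, 2)

  # iid noise never de-aliases: saturation is reported, not hidden
  w <- generate_benchmark("white", 4000, seed = 9)
  fw <- gfnn(w, delay = 1, max_dim = 5)
  expect_true(fw$saturated)
  expect_equal(fw$selected_dim, 5L)
  expect_true(all(fw$fnn_fraction > 0.10))

  expect_error(gfnn(rnorm(30), delay = 5, max_dim = 8), "need >= ")
})

test_that("delay embedding lays out lagged coordinates exactly", {
  tr <- delay_embed(1:10, dim = 2, delay = 3)
  expect_equal(dim(tr), c(7L, 2L))
  expect_equal(tr[1, ], c(1, 4))
  expect_equal(delay_embed(1:10, dim = 1, delay = 4)[, 1], as.numeric(1:10))
  tr3 <- delay_embed(1:10, dim = 3, delay = 2)
  expect_equal(dim(tr3), c(6L, 3L))
  expect_equal(tr3[6, ], c(6, 8, 10))
  expect_error(delay_embed(1:5, dim = 3, delay = 3), "too short")
  # embedding_spec carries the parameters
  sp <- embedding_spec(3, 2, "knee")
  expect_equal(delay_embed(1:10, sp), tr)
  expect_error(embedding_spec(0, 2), "delay")
})

test_that("Rosenstein exponent matches the logistic-map analytic value", {
  x <- generate_benchmark("logistic", 10000, params = list(x0 = 0.2))
  traj <- delay_embed(x, dim = 2, delay = 1)
  ly <- lyapunov_rosenstein(traj, fs = 1,
                            mean_period = estimate_mean_period(x))
  expect_equal(ly$lye, log(2), tolerance = 0.05)
})

test_that("Rosenstein exponent is near zero for periodic signals", {
  x <- generate_benchmark("sine", 6000, params = list(period = 60))
  traj <- delay_embed(x, dim = 2, delay = 15)
  ly <- lyapunov_rosenstein(traj, fs = 1,
                            mean_period = estimate_mean_period(x))
  expect_lt(abs(ly$lye), 0.05 * log(2))
})

test_that("Rosenstein exponent on Lorenz agrees with the perturbation
           oracle", {
  oracle <- lorenz_lye_oracle(n_steps = 20000)
  expect_equal(oracle, 0.906, tolerance = 0.05)  # literature cross-check
  xl <- generate_benchmark("lorenz", 20000,
                           params = list(dt = 0.01, transient = 1000))
  dl <- average_mutual_information(xl, max_lag = 100)$selected_delay
  traj <- delay_embed(xl, dim = 3, delay = dl)
  ly <- lyapunov_rosenstein(traj, fs = 100,
                            mean_period = estimate_mean_period(xl))
  expect_equal(ly$lye, oracle, tolerance = 0.15)
})

test_that("Rosenstein guards degenerate fit windows and short inputs", {
  x <- generate_benchmark("logistic", 500, params = list(x0 = 0.4))
  traj <- delay_embed(x, dim = 2, delay = 1)
  expect_error(lyapunov_rosenstein(traj, 1, mean_period = 4,
                                   fit_window = c(5, 2)), "fit_window")
  expect_error(lyapunov_rosenstein(traj, 1, mean_period = 4,
                                   fit_window = c(0, 50), max_steps = 20),
               "beyond")
  expect_error(lyapunov_rosenstein(traj[1:10, ], 1, mean_period = 4),
               "too short")
})

test_that("sample entropy equals the brute-force pair count exactly", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(60)
    r <- 0.2 * sd(x)
    fast <- sample_entropy(x, m = 2, r = r)
    slow <- sampen_brute(x, m = 2, r = r)
    expect_identical(attr(fast, "A"), as.numeric(slow$A))
    expect_identical(attr(fast, "B"), as.numeric(slow$B))
    expect_equal(as.numeric(fast), slow$sampen)
  }
})

test_that("sample entropy matches the iid Gaussian closed form", {
  # for iid data the conditional match probability is
  # P(|X - X'| <= r) = erf(r / (2 sigma)); at r = 0.2 sigma this gives
  # SampEn = -ln(erf(0.1)) ~= 2.185
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  target <- -log(erf(0.1))
  x <- generate_benchmark("white", 10000, seed = 31)
  se <- sample_entropy(x, m = 2, r = 0.2 * sd(x))
  expect_equal(as.numeric(se), target, tolerance = 0.05)

  # the closed form itself verified by brute-force counting at small n
  set.seed(32)
  ratios <- replicate(40, {
    y <- rnorm(200)
    b <- sampen_brute(y, m = 1, r = 0.2)
    b$B / choose(199, 2)  # fraction of length-1 template matches
  })
  expect_equal(mean(ratios), erf(0.1), tolerance = 0.1)
})

test_that("sample entropy edge cases return flagged sentinels", {
  cs <- sample_entropy(rep(1, 100), m = 2, r = 0.5)
  expect_equal(as.numeric(cs), 0)   # every template matches: -ln(1)
  expect_false(attr(cs, "undefined"))

  ramp <- sample_entropy(as.numeric(1:100), m = 2, r = 1e-3)
  expect_true(is.na(as.numeric(ramp)))
  expect_true(attr(ramp, "undefined"))
  expect_error(sample_entropy(1:3, m = 2, r = 1), "too short")
  expect_error(sample_entropy(rnorm(50), m = 2, r = 0), "positive")
})

test_that("sample entropy is amplitude invariant with relative tolerance", {
  x <- generate_benchmark("white", 2000, seed = 41)
  s1 <- as.numeric(sample_entropy(x, 2, 0.2 * sd(x)))
  s2 <- as.numeric(sample_entropy(7 * x, 2, 0.2 * sd(7 * x)))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("CMSE reduces to SampEn at scale 1 and sums into the CI", {
  x <- generate_benchmark("white", 2000, seed = 51)
  prof <- composite_multiscale_entropy(x, n_scales = 5)
  expect_identical(prof$cmse[1],
                   as.numeric(sample_entropy(x, 2, 0.2 * sd(x))))
  expect_equal(prof$ci, sum(prof$cmse))

  # Complexity Index arithmetic on a constant profile
  flat <- cmse_profile(rep(0.5, 20))
  expect_identical(flat$ci, 10.0)

  # undefined scales poison the CI with a flag, not an infinity
  part <- cmse_profile(c(0.5, NA), undefined_scales = c(FALSE, TRUE))
  expect_true(is.na(part$ci))
  expect_error(cmse_profile(c(0.5, Inf)), "flagged")
})

test_that("CMSE separates white from pink noise in the standard way", {
  w <- generate_benchmark("white", 4000, seed = 61)
  p <- generate_benchmark("pink", 4000, seed = 62)
  cw <- composite_multiscale_entropy(w)
  cp <- composite_multiscale_entropy(p)
  expect_lt(cor(seq_len(20), cw$cmse, method = "spearman"), 0)
  expect_gt(cp$ci, cw$ci)
})

test_that("per-joint nonlinear summary orders regular vs chaotic gait", {
  base <- list(n_strides = 45, latent_rank = 3, latent_amp_sd = 0,
               cycle_noise_sd = 0.1, sensor_noise_sd = 0.1,
               stride_duration_cv = 0)
  quiet <- generate_gait(do.call(gait_gen_config,
                                 c(base, list(chaos_mod = 0, seed = 71))))
  noisy <- generate_gait(do.call(gait_gen_config,
                                 c(base, list(chaos_mod = 0.45, seed = 71))))
  sq <- joint_nld_summary(quiet$trial,
                          joints = c("hip_L_sagittal", "knee_L_sagittal"))
  sn <- joint_nld_summary(noisy$trial,
                          joints = c("hip_L_sagittal", "knee_L_sagittal"))
  for (ch in names(sq)) {
    expect_lt(abs(sq[[ch]]$lye$lye), 0.5)       # near-periodic
    expect_gt(sn[[ch]]$lye$lye, sq[[ch]]$lye$lye)  # chaos raises LyE
  }

  expect_error(joint_nld_summary(quiet$trial, joints = "elbow_L_sagittal"),
               "available sagittal")
  short <- kin_trial(matrix(rnorm(200 * 2), 200, 2), fs = 60,
                     channels = c("hip_L_sagittal", "knee_L_sagittal"))
  expect_error(joint_nld_summary(short), "needs >= ")
})

test_that("estimators are deterministic given input and configuration", {
  g <- generate_gait(gait_gen_config(n_strides = 40, seed = 81))
  s1 <- joint_nld_summary(g$trial, joints = "hip_L_sagittal")
  s2 <- joint_nld_summary(g$trial, joints = "hip_L_sagittal")
  expect_identical(s1, s2)
})
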