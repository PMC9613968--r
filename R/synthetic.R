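default_basis_waveforms <- function(r) {
  # Latent waveform m is the pure m-th stride harmonic with a fixed phase
  # offset: distinct harmonics are orthogonal over the cycle and carry
  # equal variance (1/2), so each latent direction contributes equally -
  # the property the rank-recovery structure relies on. The fundamental
  # and low harmonics dominate real sagittal joint curves too.
  lapply(seq_len(r), function(m)
    list(amp = c(rep(0, m - 1), 1), phase = rep(0.9 * (m - 1), m)))
}

eval_basis <- function(basis, phase) {
  # returns length(phase) x r matrix of latent waveform values
  sapply(basis, function(b) {
    amp <- b$amp
    ph <- rep_len(b$phase %||% 0, length(amp))
    out <- numeric(length(phase))
    for (h in seq_along(amp))
      out <- out + amp[h] * sin(2 * pi * h * phase + ph[h])
    out
  })
}

default_loading <- function(p, r) {
  # Deterministic p x r matrix with orthonormal columns, scaled to a
  # 25-degree amplitude: combined with the equal-variance basis waveforms
  # every latent direction carries the same variance, so the noise-free
  # trial covariance has r equal nonzero eigenvalues and rank recovery by
  # the 95%-variance rule is exact whenever residual noise is small.
  M0 <- matrix(sin(seq_len(p * r) * 2.399), p, r)
  25 * qr.Q(qr(M0))
}

#' Configuration for the synthetic multi-joint gait generator
#'
#' The generator emulates the statistical structure of multi-joint
#' periodic gait: per stride, each channel is a fixed linear combination
#' (the loading matrix) of `latent_rank` periodic basis waveforms, with
#' per-stride latent amplitude jitter, additive white cycle and sensor
#' noise, and stride durations drawn with a stated coefficient of
#' variation (optionally modulated by a logistic map to inject aperiodic
#' stride timing).
#'
#' @param p number of channels; 18 gives the canonical lower-limb set.
#' @param n_strides number of strides to generate.
#' @param stride_duration_mean mean stride duration in seconds.
#' @param stride_duration_cv coefficient of variation of stride duration.
#' @param fs sampling rate in Hz.
#' @param latent_rank number of independent basis waveforms (>= 1); the
#'   noise-free trial covariance has exactly this rank.
#' @param harmonics list of `latent_rank` basis specs (`amp`, `phase`
#'   vectors over harmonics); `NULL` for gait-like defaults.
#' @param loading_matrix p x latent_rank loading (degrees); `NULL` for a
#'   structured default.
#' @param latent_amp_sd SD of the per-stride multiplicative latent
#'   amplitude jitter (unitless; 0 = identical stride waveforms).
#' @param cycle_noise_sd SD of white stride-level angle noise (degrees).
#' @param sensor_noise_sd SD of white measurement noise (degrees).
#' @param chaos_mod depth in (0, 0.5] of logistic-map modulation of stride
#'   durations; 0 disables it.
#' @param seed mandatory integer seed; the generator is a pure function of
#'   the configuration.
#' @return A validated list of class `gait_gen_config`.
#' @export
gait_gen_config <- function(p = 18, n_strides = 50,
                            stride_duration_mean = 1.1,
                            stride_duration_cv = 0.02, fs = 60,
                            latent_rank = 3, harmonics = NULL,
                            loading_matrix = NULL, latent_amp_sd = 0.05,
                            cycle_noise_sd = 0.5, sensor_noise_sd = 0.2,
                            chaos_mod = 0, seed) {
  chk <- function(ok, field, why) if (!ok)
    stop(sprintf("invalid config field '%s': %s", field, why))
  chk(is.numeric(p) && p >= 1, "p", "need >= 1 channel")
  chk(n_strides >= 1, "n_strides", "need >= 1 stride")
  chk(stride_duration_mean > 0, "stride_duration_mean", "must be positive")
  chk(stride_duration_cv >= 0, "stride_duration_cv", "must be >= 0")
  chk(fs > 0, "fs", "must be positive")
  chk(latent_rank >= 1 && latent_rank <= p, "latent_rank",
      "need 1 <= rank <= p")
  chk(latent_amp_sd >= 0, "latent_amp_sd", "must be >= 0")
  chk(cycle_noise_sd >= 0, "cycle_noise_sd", "must be >= 0")
  chk(sensor_noise_sd >= 0, "sensor_noise_sd", "must be >= 0")
  chk(chaos_mod >= 0 && chaos_mod <= 0.5, "chaos_mod", "need 0 <= depth <= 0.5")
  chk(!missing(seed) && is.numeric(seed), "seed", "a seed is mandatory")
  harmonics <- harmonics %||% default_basis_waveforms(latent_rank)
  chk(length(harmonics) == latent_rank, "harmonics",
      "need one basis spec per latent waveform")
  loading_matrix <- loading_matrix %||% default_loading(p, latent_rank)
  loading_matrix <- as.matrix(loading_matrix)
  chk(all(dim(loading_matrix) == c(p, latent_rank)), "loading_matrix",
      "must be p x latent_rank")
  structure(list(p = p, n_strides = n_strides,
                 stride_duration_mean = stride_duration_mean,
                 stride_duration_cv = stride_duration_cv, fs = fs,
                 latent_rank = latent_rank, harmonics = harmonics,
                 loading_matrix = loading_matrix,
                 latent_amp_sd = latent_amp_sd,
                 cycle_noise_sd = cycle_noise_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 chaos_mod = chaos_mod, seed = as.integer(seed)),
            class = "gait_gen_config")
}

#' Generate a synthetic multi-joint gait trial
#'
#' Produces a [kin_trial()], the matching [foot_contacts()] at stride
#' starts, and a ground-truth record sufficient to score parameter
#' recovery by every downstream measure (latent rank for dimensionality,
#' noise SD for GaitSD, timing modulation for the Lyapunov exponent,
#' loading scale for generalized variance). Stride waveforms are defined
#' on cycle phase [0, 1) so consecutive strides join continuously.
#'
#' @param config a [gait_gen_config()].
#' @param trial_id,activity_label metadata for the trial.
#' @return List with elements `trial`, `contacts`, `ground_truth`.
#' @export
generate_gait <- function(config, trial_id = "synthetic",
                          activity_label = "synthetic") {
  stopifnot(inherits(config, "gait_gen_config"))
  with_seed(config$seed, {
    ns <- config$n_strides
    dur <- rep(config$stride_duration_mean, ns)
    if (config$stride_duration_cv > 0)
      dur <- dur * (1 + config$stride_duration_cv * rnorm(ns))
    chaos_x0 <- NULL
    if (config$chaos_mod > 0) {
      chaos_x0 <- runif(1, 0.1, 0.9)
      l <- numeric(ns); l[1] <- chaos_x0
      for (i in seq_len(ns - 1)) l[i + 1] <- 4 * l[i] * (1 - l[i])
      dur <- dur * (1 + config$chaos_mod * (2 * l - 1))
    }
    dur <- pmax(dur, 0.3 * config$stride_duration_mean)
    frames <- pmax(2L, as.integer(round(dur * config$fs)))
    total <- sum(frames)
    gains <- matrix(1 + config$latent_amp_sd *
                      rnorm(ns * config$latent_rank),
                    ns, config$latent_rank)
    samples <- matrix(0, total, config$p)
    pos <- 1L
    for (i in seq_len(ns)) {
      nf <- frames[i]
      phase <- (0:(nf - 1)) / nf
      B <- eval_basis(config$harmonics, phase)           # nf x r
      lat <- B * matrix(gains[i, ], nf, config$latent_rank, byrow = TRUE)
      stride <- lat %*% t(config$loading_matrix)          # nf x p
      if (config$cycle_noise_sd > 0)
        stride <- stride + matrix(rnorm(nf * config$p,
                                        sd = config$cycle_noise_sd),
                                  nf, config$p)
      samples[pos:(pos + nf - 1), ] <- stride
      pos <- pos + nf
    }
    if (config$sensor_noise_sd > 0)
      samples <- samples + matrix(rnorm(total * config$p,
                                        sd = config$sensor_noise_sd),
                                  total, config$p)
    channels <- if (config$p == 18) canonical_channels() else
      paste0("ch", seq_len(config$p))
    trial <- kin_trial(samples, fs = config$fs, channels = channels,
                       trial_id = trial_id,
                       activity_label = activity_label)
    contacts <- foot_contacts(cumsum(c(1L, frames[-ns])), foot = "L",
                              n_frames = total)
    list(trial = trial, contacts = contacts,
         ground_truth = list(latent_rank = config$latent_rank,
                             stride_frames = frames,
                             stride_durations_s = frames / config$fs,
                             latent_amp_sd = config$latent_amp_sd,
                             cycle_noise_sd = config$cycle_noise_sd,
                             sensor_noise_sd = config$sensor_noise_sd,
                             chaos_mod = config$chaos_mod,
                             chaos_x0 = chaos_x0,
                             seed = config$seed))
  })
}

#' Configuration for two-dimensional Gaussian toy clouds
#'
#' Two Gaussian point clouds illustrating how variance-based and
#' dimensionality-based complexity can disagree: clouds with the same
#' shape but different scale share a dimensionality but not a generalized
#' variance, while a near-rank-1 cloud against an isotropic one reverses
#' the comparison.
#'
#' @param n_points points per cloud.
#' @param mean1,mean2 length-2 mean vectors.
#' @param cov1,cov2 2 x 2 symmetric positive semi-definite covariances.
#' @param seed mandatory integer seed.
#' @return A validated list of class `toy_cloud_config`.
#' @export
toy_cloud_config <- function(n_points = 5000, mean1 = c(0, 0),
                             mean2 = c(0, 0), cov1 = diag(2),
                             cov2 = diag(2), seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("invalid config field 'seed': a seed is mandatory")
  if (n_points < 1) stop("invalid config field 'n_points': need >= 1")
  for (nm in c("cov1", "cov2")) {
    S <- get(nm)
    if (!isTRUE(all.equal(S, t(S))) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
      stop(sprintf("invalid config field '%s': not symmetric positive semi-definite",
                   nm))
  }
  structure(list(n_points = n_points, mean1 = mean1, mean2 = mean2,
                 cov1 = cov1, cov2 = cov2, seed = as.integer(seed)),
            class = "toy_cloud_config")
}

#' Generate the two Gaussian toy clouds
#'
#' @param config a [toy_cloud_config()].
#' @return List with `cloud1` and `cloud2`, each an n x 2 matrix.
#' @export
generate_toy_clouds <- function(config) {
  stopifnot(inherits(config, "toy_cloud_config"))
  with_seed(config$seed, {
    list(cloud1 = MASS::mvrnorm(config$n_points, config$mean1, config$cov1),
         cloud2 = MASS::mvrnorm(config$n_points, config$mean2, config$cov2))
  })
}

#' Generate a designed suite of discordantly complex activities
#'
#' Four synthetic activities whose complexity measures provably disagree,
#' by construction:
#' \describe{
#'   \item{walk}{periodic, low-rank, low-noise baseline - the
#'     straight-line forward-walking analogue; least complex under the
#'     dimensionality, generalized-variance and entropy measures at once.}
#'   \item{highdim}{eight latent directions at modest amplitude: the
#'     most components to reach 95\% variance, but a small joint-space
#'     volume.}
#'   \item{highvar}{three latent directions at large amplitude with
#'     strong sensor noise: the largest generalized variance, but low
#'     dimensionality.}
#'   \item{irregular}{moderate amplitude with logistic-map-modulated
#'     stride timing and broadband noise: the highest multiscale-entropy
#'     Complexity Index.}
#' }
#' Running [analyze_activity()] and [rank_activities()] over the suite
#' yields three different "most complex" winners and a Kendall's W
#' below 1 - the structural form of cross-measure disagreement.
#'
#' @param seed base seed; trial seeds are derived from it.
#' @param n_trials trials per activity.
#' @param n_strides strides per trial.
#' @return Named list of activities, each a list of
#'   `list(trial, contacts, ground_truth)` elements from
#'   [generate_gait()].
#' @export
generate_discordant_activities <- function(seed, n_trials = 2,
                                           n_strides = 50) {
  ortho <- function(p, r) qr.Q(qr(matrix(sin(seq_len(p * r) * 2.399), p, r)))
  mk <- function(label, offset, ...) lapply(seq_len(n_trials), function(i)
    generate_gait(gait_gen_config(n_strides = n_strides,
                                  seed = seed + offset + i, ...),
                  trial_id = sprintf("%s_%d", label, i),
                  activity_label = label))
  list(
    walk = mk("walk", 0, latent_rank = 2,
              loading_matrix = 12 * ortho(18, 2),
              cycle_noise_sd = 0.2, sensor_noise_sd = 0.1,
              stride_duration_cv = 0.01),
    highdim = mk("highdim", 10, latent_rank = 8,
                 loading_matrix = 20 * ortho(18, 8),
                 latent_amp_sd = 0.02, cycle_noise_sd = 0.2,
                 sensor_noise_sd = 0.15),
    highvar = mk("highvar", 20, latent_rank = 3,
                 loading_matrix = 60 * ortho(18, 3),
                 cycle_noise_sd = 1, sensor_noise_sd = 3),
    irregular = mk("irregular", 30, latent_rank = 3,
                   cycle_noise_sd = 0.8, sensor_noise_sd = 0.8,
                   chaos_mod = 0.45))
}

lorenz_deriv <- function(t, state, parms) {
  with(as.list(c(state, parms)), {
    list(c(sigma * (y - x),
           x * (rho - z) - y,
           x * y - beta * z))
  })
}

#' Generate canonical benchmark signals for estimator validation
#'
#' Produces the standard test signals against which the nonlinear
#' estimators have known answers: a sinusoid (zero Lyapunov exponent,
#' planar attractor), white and 1/f pink noise (entropy-vs-scale
#' signatures), the fully chaotic logistic map (Lyapunov exponent ln 2
#' per iteration), and the x-component of the Lorenz system at the
#' classic chaotic parameters.
#'
#' @param kind one of `"sine"`, `"white"`, `"pink"`, `"logistic"`,
#'   `"lorenz"`.
#' @param n number of samples (>= 100).
#' @param params named list of kind-specific parameters: sine
#'   (`period` samples, `amplitude`, `phase`), white (`sd`), pink
#'   (`sd`), logistic (`r`, `x0`, `transient`), lorenz (`sigma`, `rho`,
#'   `beta`, `dt`, `transient` samples, `init`).
#' @param seed integer seed; required for the stochastic kinds.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' generate_benchmark("logistic", 5, params = list(x0 = 0.2, transient = 0))
generate_benchmark <- function(kind, n, params = list(), seed = NULL) {
  kinds <- c("sine", "white", "pink", "logistic", "lorenz")
  if (!is.character(kind) || !kind %in% kinds)
    stop(sprintf("unknown kind '%s'; valid kinds: %s",
                 as.character(kind)[1], paste(kinds, collapse = ", ")))
  if (n < 100) stop("need n >= 100")
  switch(kind,
    sine = {
      period <- params$period %||% 60
      amp <- params$amplitude %||% 1
      ph <- params$phase %||% 0
      amp * sin(2 * pi * (seq_len(n) - 1) / period + ph)
    },
    white = {
      if (is.null(seed)) stop("white noise needs a seed")
      with_seed(seed, rnorm(n, sd = params$sd %||% 1))
    },
    pink = {
      if (is.null(seed)) stop("pink noise needs a seed")
      with_seed(seed, {
        w <- rnorm(n)
        W <- fft(w)
        k <- seq_len(n - 1)
        f <- c(1, pmin(k, n - k))           # two-sided frequency index, DC guarded
        Wp <- W / sqrt(f)
        x <- Re(fft(Wp, inverse = TRUE)) / n
        (params$sd %||% 1) * x / sd(x)
      })
    },
    logistic = {
      r <- params$r %||% 4
      x0 <- params$x0 %||% 0.2
      transient <- params$transient %||% 1000
      total <- n + transient
      x <- numeric(total)
      x[1] <- x0
      for (i in seq_len(total - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
      x[(transient + 1):total]
    },
    lorenz = {
      dt <- params$dt %||% 0.01
      transient <- params$transient %||% 1000
      parms <- c(sigma = params$sigma %||% 10, rho = params$rho %||% 28,
                 beta = params$beta %||% (8 / 3))
      init <- params$init %||% c(x = 1, y = 1, z = 1)
      times <- seq(0, (n + transient) * dt, by = dt)
      sol <- deSolve::ode(y = init, times = times, func = lorenz_deriv,
                          parms = parms, method = "rk4")
      sol[(transient + 1):(transient + n), "x"]
    })
}
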