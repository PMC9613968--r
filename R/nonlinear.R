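#' Average mutual information between a series and its lagged copy
#'
#' Histogram-based mutual information (nats) between x(t) and x(t + lag)
#' for lags 0..`max_lag`, using `n_bins` equal-width bins spanning the
#' range of the series. The embedding delay is chosen as the first local
#' minimum of the curve (located on a lightly smoothed copy to suppress
#' binning wiggles, then refined on the raw curve); when no local minimum
#' exists within `max_lag` (flat curves, e.g. white noise) the argmin
#' over lags >= 1 is used and `fallback_used` is set.
#'
#' @param x numeric series (not constant).
#' @param max_lag largest lag to evaluate; defaults to `min(100, n/10)`.
#' @param n_bins number of histogram bins; defaults to
#'   `max(16, ceiling(n^(1/3)))`.
#' @return An object of class `ami_curve` with fields `lags` (0..max_lag),
#'   `ami` (nats), `selected_delay`, `fallback_used`.
#' @export
#' @examples
#' x <- sin(2 * pi * (1:3000) / 60)
#' average_mutual_information(x)$selected_delay  # quarter period = 15
average_mutual_information <- function(x, max_lag = NULL, n_bins = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) stop("series too short for mutual information")
  if (max(x) == min(x)) stop("zero-entropy input: series is constant")
  max_lag <- max_lag %||% max(2L, min(100L, n %/% 10L))
  if (n < 2 * max_lag) stop("series shorter than twice max_lag")
  n_bins <- n_bins %||% max(16L, ceiling(n^(1 / 3)))
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  ami <- numeric(max_lag + 1)
  for (lag in 0:max_lag) {
    b1 <- bin[seq_len(n - lag)]
    b2 <- bin[seq_len(n - lag) + lag]
    joint <- tabulate(b1 + n_bins * (b2 - 1L), nbins = n_bins * n_bins)
    pj <- joint / sum(joint)
    pm <- matrix(pj, n_bins, n_bins)
    px <- rowSums(pm)
    py <- colSums(pm)
    nz <- pm > 0
    ami[lag + 1] <- sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
  }
  # Binning produces small wiggles on the MI curve, so the first local
  # minimum is located on a short moving-average smooth and then refined
  # to the raw-curve argmin in its +/-2 lag neighbourhood. A local min at
  # lag t needs the curve decreasing into t and increasing out of it; the
  # last lag never qualifies (no right neighbour).
  first_local_min <- function(y) {
    d <- diff(y)
    cand <- which(d < 0 & c(d[-1], -Inf) > 0)
    if (length(cand)) cand[1] else NA_integer_
  }
  sm <- if (max_lag >= 7) {
    vapply(seq_along(ami), function(i)
      mean(ami[max(1, i - 2):min(length(ami), i + 2)]), numeric(1))
  } else ami
  loc <- first_local_min(sm)
  fallback <- is.na(loc)
  selected <- if (fallback) {
    which.min(ami[-1])
  } else {
    nb <- max(1, loc - 2):min(max_lag, loc + 2)
    nb[which.min(ami[nb + 1])]
  }
  structure(list(lags = 0:max_lag, ami = ami,
                 selected_delay = as.integer(selected),
                 fallback_used = fallback),
            class = "ami_curve")
}

#' @export
print.ami_curve <- function(x, ...) {
  cat(sprintf("<ami_curve> lags 0..%d, selected delay %d%s\n",
              max(x$lags), x$selected_delay,
              if (x$fallback_used) " (argmin fallback)" else ""))
  invisible(x)
}

#' Global false nearest neighbours embedding-dimension selection
#'
#' Kennel-criterion false-neighbour fractions per candidate dimension: for
#' each delay vector the nearest neighbour in d dimensions is found and
#' declared false if adding the (d+1)-th coordinate separates the pair,
#' either relative to the neighbour distance (`r_tol`) or relative to the
#' attractor size (`a_tol`, with attractor size taken as the SD of the
#' series). The selected dimension is the smallest with a false-neighbour
#' fraction below `threshold`; if none qualifies (noise-like input) the
#' largest candidate is reported with `saturated = TRUE`. Temporal
#' neighbours within a Theiler window (the delay, by default) are
#' excluded from the search so oversampled trajectories do not hide false
#' neighbours behind their own recent past. For long series the
#' nearest-neighbour search uses an evenly spaced subsample of reference
#' vectors (`n_ref`), searched against all vectors.
#'
#' @param x numeric series.
#' @param delay embedding delay in samples (e.g. from
#'   [average_mutual_information()]).
#' @param max_dim largest dimension to test.
#' @param r_tol,a_tol Kennel test tolerances.
#' @param threshold acceptable false-neighbour fraction (default 10%).
#' @param n_ref cap on the number of reference vectors.
#' @param theiler temporal exclusion window in samples (default: the
#'   delay).
#' @return An object of class `fnn_curve` with fields `dims`,
#'   `fnn_fraction`, `selected_dim`, `saturated`.
#' @export
gfnn <- function(x, delay, max_dim = 8, r_tol = 15, a_tol = 2,
                 threshold = 0.10, n_ref = 2000, theiler = NULL) {
  theiler <- theiler %||% delay
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(delay >= 1, max_dim >= 1)
  min_len <- max_dim * delay + 10
  if (n < min_len)
    stop(sprintf("series too short for max_dim %d at delay %d: need >= %d samples",
                 max_dim, delay, min_len))
  asize <- sd(x)
  if (asize == 0) stop("constant series has no attractor")
  frac <- numeric(max_dim)
  for (d in seq_len(max_dim)) {
    m_valid <- n - d * delay      # vectors that also exist at dimension d+1
    refs <- if (m_valid > n_ref)
      unique(round(seq(0, m_valid - 1, length.out = n_ref))) else
        0:(m_valid - 1)
    res <- fnn_fraction_cpp(x, delay, d, r_tol, a_tol, asize,
                            as.integer(refs), as.integer(theiler))
    frac[d] <- if (res$n_used > 0) res$n_false / res$n_used else NA_real_
  }
  below <- which(frac < threshold)
  saturated <- length(below) == 0
  structure(list(dims = seq_len(max_dim), fnn_fraction = frac,
                 selected_dim = if (saturated) max_dim else below[1],
                 saturated = saturated),
            class = "fnn_curve")
}

#' @export
print.fnn_curve <- function(x, ...) {
  cat(sprintf("<fnn_curve> dims 1..%d, selected %d%s\n",
              max(x$dims), x$selected_dim,
              if (x$saturated) " (saturated: no dim below threshold)" else ""))
  invisible(x)
}

#' Embedding parameters for state-space reconstruction
#'
#' @param delay delay in samples (>= 1).
#' @param dim embedding dimension (>= 1).
#' @param series_id identifying label.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(delay, dim, series_id = "") {
  delay <- as.integer(delay); dim <- as.integer(dim)
  if (delay < 1) stop("delay must be >= 1")
  if (dim < 1) stop("dim must be >= 1")
  structure(list(delay = delay, dim = dim, series_id = series_id),
            class = "embedding_spec")
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat(sprintf("<embedding_spec> dim %d, delay %d%s\n", x$dim, x$delay,
              if (nzchar(x$series_id)) paste0(" (", x$series_id, ")") else ""))
  invisible(x)
}

#' Delay-embed a scalar series into a trajectory matrix
#'
#' Row i of the result is `[x(i), x(i+delay), ..., x(i+(dim-1)*delay)]`;
#' there are `length(x) - (dim-1)*delay` rows.
#'
#' @param x numeric series.
#' @param dim embedding dimension, or an [embedding_spec()] (then `delay`
#'   is ignored).
#' @param delay embedding delay in samples.
#' @return Numeric matrix M x dim.
#' @export
#' @examples
#' delay_embed(1:10, dim = 2, delay = 3)
delay_embed <- function(x, dim, delay = 1) {
  if (inherits(dim, "embedding_spec")) {
    delay <- dim$delay
    dim <- dim$dim
  }
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(dim >= 1, delay >= 1)
  if ((dim - 1) * delay >= n)
    stop("series too short: need (dim - 1) * delay < length(x)")
  M <- n - (dim - 1) * delay
  out <- matrix(NA_real_, M, dim)
  for (k in seq_len(dim)) out[, k] <- x[seq_len(M) + (k - 1) * delay]
  out
}

#' Mean period of a series from its power spectrum
#'
#' The reciprocal of the power-weighted mean frequency of the raw
#' periodogram, in samples. Robust for broadband (chaotic or noisy)
#' signals where the location of the single largest periodogram peak is
#' erratic; used as the Theiler-window scale for neighbour searches.
#'
#' @param x numeric series.
#' @return Period in samples.
#' @export
estimate_mean_period <- function(x) {
  pg <- stats::spec.pgram(as.numeric(x), plot = FALSE, detrend = TRUE,
                          taper = 0)
  sum(pg$spec) / sum(pg$freq * pg$spec)
}

#' Largest Lyapunov exponent by the Rosenstein method
#'
#' For every reconstructed state the nearest neighbour outside a Theiler
#' window (one mean period by default) is found; the mean natural log of
#' the pairwise distance is tracked forward in time and the exponent is
#' the least-squares slope of that divergence curve over `fit_window`,
#' converted to units of 1/second by multiplying by the sampling rate.
#' Positive values indicate exponential divergence (aperiodic dynamics);
#' values near zero indicate periodic dynamics.
#'
#' The default fit window spans half to two mean periods: the first
#' half-period of the curve is dominated by the transient in which
#' imperfectly aligned neighbour pairs rotate into the most expanding
#' direction and systematically over-states the exponent, while beyond a
#' few mean periods the curve saturates at the attractor size.
#'
#' @param traj trajectory matrix from [delay_embed()].
#' @param fs sampling rate of the underlying series (Hz); use 1 for maps
#'   so the exponent is per iteration.
#' @param mean_period dominant period in samples (see
#'   [estimate_mean_period()]); sets the default Theiler window and fit
#'   window.
#' @param fit_window integer `c(first, last)` divergence steps used for
#'   the slope fit; default `c(round(mean_period / 2), round(2 * mean_period))`.
#' @param theiler Theiler exclusion window in samples; default one mean
#'   period.
#' @param max_steps how far to track divergence; default covers the fit
#'   window and one mean period.
#' @return An object of class `lye_result` with fields `lye` (1/s),
#'   `divergence_curve` (mean ln distance per step, step 0 first),
#'   `fit_window`, `theiler_window`, `fs`.
#' @export
lyapunov_rosenstein <- function(traj, fs, mean_period,
                                fit_window = NULL, theiler = NULL,
                                max_steps = NULL) {
  traj <- as.matrix(traj)
  M <- nrow(traj)
  if (!is.numeric(mean_period) || mean_period <= 0)
    stop("mean_period must be positive")
  theiler <- theiler %||% max(1L, round(mean_period))
  fit_window <- fit_window %||%
    c(max(1, round(mean_period / 2)), max(3, round(2 * mean_period)))
  fit_window <- as.integer(round(fit_window))
  if (length(fit_window) != 2 || fit_window[1] < 0 ||
      fit_window[2] <= fit_window[1])
    stop("fit_window must be increasing non-negative steps c(first, last)")
  max_steps <- max_steps %||% max(fit_window[2], round(mean_period))
  max_steps <- as.integer(max_steps)
  if (fit_window[2] > max_steps)
    stop("fit window extends beyond the tracked divergence curve")
  if (M - max_steps < theiler + 2)
    stop("trajectory too short for the requested Theiler window and steps")
  res <- rosenstein_divergence_cpp(traj, as.integer(theiler), max_steps)
  curve <- ifelse(res$count > 0, res$log_sum / res$count, NA_real_)
  if (all(res$count == 0)) stop("no valid neighbour pairs found")
  steps <- fit_window[1]:fit_window[2]
  y <- curve[steps + 1]
  ok <- is.finite(y)
  if (sum(ok) < 2) stop("divergence curve undefined over the fit window")
  slope <- cov(steps[ok], y[ok]) / var(steps[ok])
  structure(list(lye = slope * fs, divergence_curve = curve,
                 fit_window = fit_window, theiler_window = theiler,
                 fs = fs),
            class = "lye_result")
}

#' @export
print.lye_result <- function(x, ...) {
  cat(sprintf("<lye_result> LyE = %.4g /s (fit steps %d..%d, Theiler %d)\n",
              x$lye, x$fit_window[1], x$fit_window[2], x$theiler_window))
  invisible(x)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) where B counts pairs of length-m templates
#' within Chebyshev distance r and A counts pairs of length-(m+1)
#' templates, self-matches excluded (N - m templates at both lengths).
#' When no templates match at either length the value is undefined and
#' `NA` is returned with attribute `undefined = TRUE` - never a silent
#' infinity.
#'
#' @param x numeric series, length > m + 1.
#' @param m template length (default 2).
#' @param r absolute tolerance (same units as `x`).
#' @return Numeric SampEn in nats, with attributes `A`, `B`, and
#'   `undefined`.
#' @export
sample_entropy <- function(x, m = 2, r) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short: need length > m + 1")
  if (!is.numeric(r) || r <= 0) stop("tolerance r must be positive")
  cnt <- sampen_counts_cpp(x, as.integer(m), r)
  A <- cnt[1]; B <- cnt[2]
  undefined <- !is.finite(A) || !is.finite(B) || B == 0 || A == 0
  val <- if (undefined) NA_real_ else -log(A / B)
  structure(val, A = A, B = B, undefined = undefined)
}

#' Composite multiscale entropy and the Complexity Index
#'
#' At scale tau the series is coarse-grained into non-overlapping windows
#' of tau samples; the composite estimate averages the sample entropy of
#' all tau possible window offsets (a variance-reduced variant of plain
#' multiscale entropy). The tolerance r is fixed at `r_factor` times the
#' SD of the original, uncoarsened series across all scales. The
#' Complexity Index is the sum of the per-scale entropies over scales
#' 1..`n_scales` (default 20, with m = 2 and r_factor = 0.2).
#'
#' Offsets whose entropy is undefined (no template matches) are dropped
#' from the per-scale mean; a scale where every offset is undefined makes
#' the CI itself undefined (`NA`), with per-scale flags retained.
#'
#' @param x numeric series.
#' @param m template length.
#' @param r_factor tolerance as a fraction of SD(x).
#' @param n_scales number of time scales.
#' @return An object of class `cmse_profile` with fields `scales`, `cmse`,
#'   `m`, `r`, `ci`, `undefined_scales`.
#' @export
composite_multiscale_entropy <- function(x, m = 2, r_factor = 0.2,
                                         n_scales = 20) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10 * n_scales)
    stop(sprintf("series too short for %d scales: need >= %d samples",
                 n_scales, 10 * n_scales))
  r <- r_factor * sd(x)
  if (r == 0) stop("constant series: tolerance would be zero")
  cmse <- numeric(n_scales)
  undef <- logical(n_scales)
  for (tau in seq_len(n_scales)) {
    vals <- numeric(tau)
    for (k in seq_len(tau)) {
      nb <- (n - k + 1) %/% tau
      y <- if (tau == 1) x else
        colMeans(matrix(x[k:(k + nb * tau - 1)], nrow = tau))
      vals[k] <- as.numeric(sample_entropy(y, m = m, r = r))
    }
    ok <- is.finite(vals)
    undef[tau] <- !any(ok)
    cmse[tau] <- if (any(ok)) mean(vals[ok]) else NA_real_
  }
  cmse_profile(cmse, m = m, r = r, undefined_scales = undef)
}

#' Assemble a composite multiscale entropy profile
#'
#' Bundles per-scale entropy values with their parameters and computes
#' the Complexity Index as the sum of the per-scale entropies over all
#' scales; the CI is undefined (`NA`) when any scale is flagged
#' undefined.
#'
#' @param cmse numeric vector of per-scale entropies (scale 1 first).
#' @param m template length used.
#' @param r absolute tolerance used.
#' @param undefined_scales logical vector flagging scales where every
#'   coarse-grained offset had no template matches.
#' @return An object of class `cmse_profile`.
#' @export
cmse_profile <- function(cmse, m = 2, r = NA_real_,
                         undefined_scales = rep(FALSE, length(cmse))) {
  stopifnot(length(cmse) >= 1, length(undefined_scales) == length(cmse))
  if (any(is.infinite(cmse)))
    stop("infinite entropy values must be flagged undefined, not passed on")
  ci <- if (any(undefined_scales)) NA_real_ else sum(cmse)
  structure(list(scales = seq_along(cmse), cmse = cmse, m = m, r = r,
                 ci = ci, undefined_scales = undefined_scales),
            class = "cmse_profile")
}

#' @export
print.cmse_profile <- function(x, ...) {
  cat(sprintf("<cmse_profile> %d scales (m = %d, r = %.4g), CI = %s\n",
              length(x$scales), x$m, x$r,
              if (is.na(x$ci)) "undefined" else sprintf("%.4g", x$ci)))
  invisible(x)
}

#' Default configuration for per-joint nonlinear-dynamics analysis
#'
#' @param max_lag largest AMI lag.
#' @param n_bins AMI histogram bins (`NULL` = data-driven default).
#' @param max_dim largest embedding dimension tested by GFNN.
#' @param fnn_threshold acceptable false-neighbour fraction.
#' @param r_tol,a_tol Kennel tolerances.
#' @param n_ref GFNN reference-vector cap.
#' @param m,r_factor,n_scales sample-entropy / CMSE parameters.
#' @param min_samples shortest series the summary will analyze.
#' @param fit_window,theiler Rosenstein overrides (`NULL` = defaults from
#'   the estimated mean period).
#' @return A named list of class `nld_config`.
#' @export
nld_config <- function(max_lag = NULL, n_bins = NULL, max_dim = 8,
                       fnn_threshold = 0.10, r_tol = 15, a_tol = 2,
                       n_ref = 2000, m = 2, r_factor = 0.2, n_scales = 20,
                       min_samples = 500, fit_window = NULL, theiler = NULL) {
  structure(list(max_lag = max_lag, n_bins = n_bins, max_dim = max_dim,
                 fnn_threshold = fnn_threshold, r_tol = r_tol, a_tol = a_tol,
                 n_ref = n_ref, m = m, r_factor = r_factor,
                 n_scales = n_scales, min_samples = min_samples,
                 fit_window = fit_window, theiler = theiler),
            class = "nld_config")
}

#' Nonlinear-dynamics summary for the sagittal-plane joints of a trial
#'
#' Runs the full state-space pipeline per channel - AMI delay selection,
#' GFNN dimension selection, delay embedding, Rosenstein largest Lyapunov
#' exponent - and, independently, composite multiscale entropy with its
#' Complexity Index on the raw scalar series. By default the sagittal
#' hip, knee and ankle channels are analyzed, the joints on which
#' state-space gait measures are conventionally computed.
#'
#' @param trial a [kin_trial()] object.
#' @param joints channel labels to analyze; default all sagittal channels
#'   present in the trial.
#' @param config an [nld_config()].
#' @return Named list (class `nld_summary`), one element per channel, each
#'   holding `embedding` ([embedding_spec()]), `ami` (`ami_curve`),
#'   `fnn` (`fnn_curve`), `lye` (`lye_result`), `cmse` (`cmse_profile`),
#'   `mean_period` (samples).
#' @export
joint_nld_summary <- function(trial, joints = NULL, config = nld_config()) {
  stopifnot(inherits(trial, "kin_trial"))
  sag <- grep("_sagittal$", trial$channels, value = TRUE)
  joints <- joints %||% sag
  missing_ch <- setdiff(joints, trial$channels)
  if (length(missing_ch) > 0)
    stop(sprintf("channel(s) %s not in trial; available sagittal channels: %s",
                 paste(missing_ch, collapse = ", "),
                 paste(sag, collapse = ", ")))
  n <- nrow(trial$samples)
  if (n < config$min_samples)
    stop(sprintf("trial has %d samples; nonlinear analysis needs >= %d",
                 n, config$min_samples))
  out <- lapply(joints, function(ch) {
    x <- trial$samples[, ch]
    ami <- average_mutual_information(x, max_lag = config$max_lag,
                                      n_bins = config$n_bins)
    fnn <- gfnn(x, delay = ami$selected_delay, max_dim = config$max_dim,
                r_tol = config$r_tol, a_tol = config$a_tol,
                threshold = config$fnn_threshold, n_ref = config$n_ref)
    spec <- embedding_spec(ami$selected_delay, fnn$selected_dim,
                           series_id = ch)
    traj <- delay_embed(x, spec)
    mp <- estimate_mean_period(x)
    lye <- lyapunov_rosenstein(traj, fs = trial$fs, mean_period = mp,
                               fit_window = config$fit_window,
                               theiler = config$theiler)
    cm <- composite_multiscale_entropy(x, m = config$m,
                                       r_factor = config$r_factor,
                                       n_scales = config$n_scales)
    list(embedding = spec, ami = ami, fnn = fnn, lye = lye, cmse = cm,
         mean_period = mp)
  })
  names(out) <- joints
  class(out) <- "nld_summary"
  out
}

#' @export
print.nld_summary <- function(x, ...) {
  cat(sprintf("<nld_summary> %d channel(s)\n", length(x)))
  for (ch in names(x)) {
    el <- x[[ch]]
    cat(sprintf("  %s: dim %d, delay %d, LyE %.3g /s, CI %s\n",
                ch, el$embedding$dim, el$embedding$delay, el$lye$lye,
                if (is.na(el$cmse$ci)) "undefined" else
                  sprintf("%.3g", el$cmse$ci)))
  }
  invisible(x)
}
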