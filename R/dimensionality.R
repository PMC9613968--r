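#' PCA variance spectrum of a multichannel signal
#'
#' Columns are mean-centred and the eigenvalues of the sample covariance
#' (divisor n - 1) are returned in descending order, together with the
#' percent of total variance carried by each principal component and the
#' cumulative percent. Because joint angles share units (degrees), the
#' covariance matrix is used directly - no standardization to unit
#' variance - so absolute as well as relative variance is meaningful.
#'
#' @param data numeric matrix, frames x channels.
#' @return An object of class `variance_spectrum` with fields
#'   `eigenvalues` (degrees^2, descending), `percent`,
#'   `cumulative_percent`, and `constant` (TRUE when the input had no
#'   variance at all).
#' @export
#' @examples
#' vs <- variance_spectrum(cbind(rnorm(500), rnorm(500, sd = 2)))
#' vs$percent
variance_spectrum <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 frames")
  S <- cov(data)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)  # clamp numerical negatives of a PSD matrix
  tot <- sum(ev)
  constant <- tot == 0
  if (constant) {
    warning("constant input: all eigenvalues are zero")
    pct <- rep(0, length(ev))
  } else {
    pct <- ev / tot * 100
  }
  structure(list(eigenvalues = ev, percent = pct,
                 cumulative_percent = cumsum(pct), constant = constant),
            class = "variance_spectrum")
}

#' @export
print.variance_spectrum <- function(x, ...) {
  cat(sprintf("<variance_spectrum> %d components, total variance %.4g\n",
              length(x$eigenvalues), sum(x$eigenvalues)))
  k <- min(6, length(x$eigenvalues))
  cat(sprintf("  leading percent: %s%s\n",
              paste(sprintf("%.1f", x$percent[seq_len(k)]), collapse = ", "),
              if (length(x$percent) > k) ", ..." else ""))
  invisible(x)
}

#' Dimensionality as the number of components explaining 95% of variance
#'
#' Returns the smallest k such that the cumulative percent variance of the
#' first k principal components reaches `threshold` (>= comparison). For a
#' perfectly isotropic p-channel spectrum this is p, since (p-1)/p of the
#' variance falls short of 95% whenever p <= 19.
#'
#' @param spectrum a [variance_spectrum()].
#' @param threshold fraction of variance to explain (default 0.95).
#' @return Integer dimensionality.
#' @export
n95 <- function(spectrum, threshold = 0.95) {
  stopifnot(inherits(spectrum, "variance_spectrum"))
  if (spectrum$constant || sum(spectrum$eigenvalues) == 0)
    stop("degenerate data: all-zero variance spectrum")
  stopifnot(threshold > 0, threshold <= 1)
  which(spectrum$cumulative_percent >= threshold * 100 - 1e-9)[1]
}

#' Per-activity aggregate of trial dimensionality
#'
#' Computes the 95%-variance dimensionality independently for each trial
#' and reports mean and standard deviation across trials. A pooled mode
#' concatenates all trials' frames into one matrix before a single PCA.
#'
#' @param trials list of [kin_trial()] objects (>= 1).
#' @param threshold variance fraction passed to [n95()].
#' @param pooled if TRUE also report the pooled-PCA dimensionality.
#' @return List with `per_trial` (named integer vector), `mean`, `sd`
#'   (0 for a single trial), and `pooled` (integer or NULL).
#' @export
activity_n95 <- function(trials, threshold = 0.95, pooled = FALSE) {
  if (length(trials) < 1) stop("need at least 1 trial")
  vals <- vapply(trials, function(tr) {
    stopifnot(inherits(tr, "kin_trial"))
    n95(variance_spectrum(tr$samples), threshold)
  }, integer(1))
  names(vals) <- vapply(trials, function(tr) tr$trial_id, character(1))
  pooled_n <- NULL
  if (pooled) {
    all_frames <- do.call(rbind, lapply(trials, function(tr) tr$samples))
    pooled_n <- n95(variance_spectrum(all_frames), threshold)
  }
  list(per_trial = vals, mean = mean(vals),
       sd = if (length(vals) > 1) sd(vals) else 0,
       pooled = pooled_n)
}
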