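#' Generalized variance of a multichannel signal
#'
#' The determinant of the sample covariance matrix of the joint angles: a
#' volume-like measure of how much of configuration space the movement
#' occupies. The determinant of an 18 x 18 covariance in degrees^2 spans
#' hundreds of orders of magnitude, so the natural log (`log_gv`) and the
#' geometric mean of the per-component variances (`normalized_gv` =
#' gv^(1/p), degrees^2) are also returned as the numerically sane
#' reporting forms.
#'
#' @param data numeric matrix, frames x channels.
#' @param eps_rank relative eigenvalue tolerance below which the covariance
#'   is declared rank-deficient (gv reported as 0).
#' @return An object of class `gv_result` with fields `gv`, `log_gv`,
#'   `normalized_gv`, `rank_deficient`, `p`.
#' @export
#' @examples
#' generalized_variance(cbind(rnorm(2000), rnorm(2000, sd = 2)))
generalized_variance <- function(data, eps_rank = 1e-10) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 frames")
  p <- ncol(data)
  ev <- eigen(cov(data), symmetric = TRUE, only.values = TRUE)$values
  rank_deficient <- ev[p] < eps_rank * max(ev[1], 0) || ev[p] <= 0
  if (rank_deficient) {
    gv <- 0
    log_gv <- -Inf
    norm_gv <- 0
  } else {
    log_gv <- sum(log(ev))   # product of eigenvalues, overflow-safe
    gv <- exp(log_gv)
    norm_gv <- exp(log_gv / p)
  }
  structure(list(gv = gv, log_gv = log_gv, normalized_gv = norm_gv,
                 rank_deficient = rank_deficient, p = p),
            class = "gv_result")
}

#' @export
print.gv_result <- function(x, ...) {
  if (x$rank_deficient) {
    cat(sprintf("<gv_result> rank-deficient covariance (p = %d): gv = 0\n",
                x$p))
  } else {
    cat(sprintf("<gv_result> p = %d, log GV = %.4f, GV^(1/p) = %.4g deg^2\n",
                x$p, x$log_gv, x$normalized_gv))
  }
  invisible(x)
}

#' Stride-to-stride waveform variability (GaitSD)
#'
#' For each joint k the squared deviation of every time-normalized cycle
#' from the mean cycle is pooled over all T phase points and N cycles:
#' \deqn{GVSD^2_k = \sum_{j=1}^{T} \sum_{i=1}^{N} (X_{ij} - \bar X_j)^2 / (T (N-1))}
#' The scalar GaitSD combines the per-joint values either as the mean of
#' the per-joint SDs (`mean_of_sd`, the default) or as the square root of
#' the mean of the per-joint variances (`sqrt_of_mean`). The two agree
#' when variability is homogeneous across joints and diverge when it is
#' not (the mean of SDs is never larger, by Jensen's inequality).
#'
#' @param cs a [cycle_set()] with N >= 2 cycles.
#' @param combiner how to collapse per-joint GVSD into one scalar.
#' @return An object of class `gait_sd_result` with fields
#'   `gvsd_sq_per_joint` (degrees^2), `gait_sd` (degrees), `n_cycles`,
#'   `combiner`.
#' @export
gait_sd <- function(cs, combiner = c("mean_of_sd", "sqrt_of_mean")) {
  stopifnot(inherits(cs, "cycle_set"))
  combiner <- match.arg(combiner)
  d <- dim(cs$cycles)
  N <- d[1]; T_pts <- d[2]; p <- d[3]
  if (N < 2) stop("need >= 2 cycles to measure stride-to-stride variability")
  gvsd_sq <- numeric(p)
  for (k in seq_len(p)) {
    xk <- cs$cycles[, , k, drop = TRUE]          # N x T
    if (N == 1) xk <- matrix(xk, nrow = 1)
    dev <- sweep(xk, 2, colMeans(xk))
    gvsd_sq[k] <- sum(dev^2) / (T_pts * (N - 1))
  }
  names(gvsd_sq) <- dimnames(cs$cycles)[[3]]
  gs <- switch(combiner,
               mean_of_sd = mean(sqrt(gvsd_sq)),
               sqrt_of_mean = sqrt(mean(gvsd_sq)))
  structure(list(gvsd_sq_per_joint = gvsd_sq, gait_sd = gs,
                 n_cycles = N, combiner = combiner),
            class = "gait_sd_result")
}

#' @export
print.gait_sd_result <- function(x, ...) {
  cat(sprintf("<gait_sd_result> GaitSD = %.4g deg over %d cycles (%s, %d joints)\n",
              x$gait_sd, x$n_cycles, x$combiner,
              length(x$gvsd_sq_per_joint)))
  invisible(x)
}
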