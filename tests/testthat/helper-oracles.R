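# Independent oracles used to cross-check the package implementations.
# These are intentionally naive (loops, direct definitions) and must stay
# independent of the code paths they verify.

# O(n^2) direct-definition sample entropy: count template pairs at lengths
# m and m + 1 under the Chebyshev norm, self-matches excluded.
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       sampen = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# Benettin-style two-trajectory perturbation-growth estimate of the
# largest Lyapunov exponent of the Lorenz system: a reference and a
# nearby trajectory are integrated with the same fixed-step RK4, the log
# separation growth is accumulated and the perturbation renormalized.
lorenz_lye_oracle <- function(n_steps = 20000, dt = 0.01, d0 = 1e-8,
                              renorm_every = 10) {
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - (8 / 3) * s[3])
  rk4 <- function(s) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(1, 1, 1)
  for (i in 1:2000) s <- rk4(s)              # transient
  s2 <- s + c(d0, 0, 0)
  acc <- 0
  for (i in seq_len(n_steps)) {
    s <- rk4(s); s2 <- rk4(s2)
    if (i %% renorm_every == 0) {
      d <- sqrt(sum((s2 - s)^2))
      acc <- acc + log(d / d0)
      s2 <- s + (s2 - s) / d * d0
    }
  }
  acc / (n_steps * dt)
}

# A tiny two-channel trial written to CSV, for loader tests.
write_tiny_trial_csv <- function(path, values = NULL) {
  df <- data.frame(
    time = c(0, 1 / 60, 2 / 60),
    hip_L_sagittal = values %||% c(10, 11, 12),
    knee_L_sagittal = c(20, 21, 22))
  write.csv(df, path, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
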