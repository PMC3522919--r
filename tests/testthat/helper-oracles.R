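# Independent oracles and fixture builders shared across test files.

# Brute-force context-weighted fuzzy c-means: plain scalar loops, same
# seeded initialization contract as the package (uniform memberships
# rescaled per column), run to a tight tolerance. Kept deliberately
# unvectorized and separate from the package code path.
brute_force_cfcm <- function(x, w, c_, m = 2, tol = 1e-12, max_iter = 2000,
                             seed = NULL) {
  run <- function() {
    N <- nrow(x)
    d <- ncol(x)
    U <- matrix(runif(c_ * N), c_, N)
    for (k in seq_len(N)) U[, k] <- U[, k] / sum(U[, k]) * w[k]
    V <- matrix(0, c_, d)
    for (iter in seq_len(max_iter)) {
      for (i in seq_len(c_)) {
        num <- rep(0, d)
        den <- 0
        for (k in seq_len(N)) {
          num <- num + U[i, k]^m * x[k, ]
          den <- den + U[i, k]^m
        }
        V[i, ] <- num / den
      }
      Unew <- U
      for (k in seq_len(N)) {
        dist2 <- sapply(seq_len(c_), function(i) sum((x[k, ] - V[i, ])^2))
        if (any(dist2 == 0)) {
          Unew[, k] <- 0
          Unew[dist2 == 0, k] <- w[k] / sum(dist2 == 0)
        } else {
          for (i in seq_len(c_)) {
            Unew[i, k] <- w[k] / sum((dist2[i] / dist2)^(1 / (m - 1)))
          }
        }
      }
      if (max(abs(Unew - U)) < tol) {
        U <- Unew
        break
      }
      U <- Unew
    }
    list(centers = V, memberships = U)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Exact unit-amplitude triangle wave with the given period, sampled at
# `rate` Hz over `seconds` seconds; zeros land exactly on samples when
# rate * period is a multiple of 2.
triangle_wave <- function(seconds, rate, period = 0.5, amplitude = 1) {
  t <- seq(0, seconds, by = 1 / rate)
  t <- t[t < seconds]
  phase <- (t / period) %% 1
  s <- ifelse(phase < 0.25, 4 * phase,
              ifelse(phase < 0.75, 2 - 4 * phase, 4 * phase - 4))
  amplitude * s
}

# Hand-built model with chosen break points, centers and coefficients, for
# oracle comparisons that bypass training. Normalization defaults to the
# identity on [0, 1].
toy_model <- function(break_points, centers, coefficients, bias = 0,
                      variant = "tsk", m = 2, d = ncol(centers[[1]])) {
  bp <- matrix(break_points, ncol = 3,
               dimnames = list(NULL, c("r_minus", "r_mode", "r_plus")))
  ctx <- structure(
    list(break_points = bp, scheme = "uniform", range = c(0, 1)),
    class = "context_set"
  )
  preds <- paste0("x", seq_len(d))
  tsklm:::new_tsklm(
    variant = variant, contexts = ctx, centers = centers, m = m,
    coefficients = matrix(coefficients, nrow = nrow(bp), byrow = TRUE,
                          dimnames = list(NULL, preds)),
    bias = bias,
    normalization = list(
      x_min = stats::setNames(rep(0, d), preds),
      x_max = stats::setNames(rep(1, d), preds),
      y_min = 0, y_max = 1
    ),
    response = "y", predictors = preds
  )
}
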