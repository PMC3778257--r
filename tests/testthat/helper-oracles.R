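# Independent oracles used across the suite. These re-derive expected
# values by brute force and must stay independent of the package code paths
# they check.

# Exact soft-margin SVM dual optimum by active-set enumeration: every
# variable is at 0, at C, or free; free variables solve the stationarity
# system on that face. The global maximum of the concave dual lies among
# the feasible candidates. Suitable for n <= ~8 points.
svm_dual_oracle <- function(X, y, C) {
  n <- length(y)
  Q <- (y %o% y) * (X %*% t(X))
  dual_obj <- function(a) sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  best <- -Inf
  states <- as.matrix(expand.grid(rep(list(0:2), n)))
  for (row in seq_len(nrow(states))) {
    st <- states[row, ]
    Fr <- which(st == 1L)
    Up <- which(st == 2L)
    alpha <- numeric(n)
    alpha[Up] <- C
    if (length(Fr)) {
      A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], y[Fr]), c(y[Fr], 0))
      upper_term <- if (length(Up)) {
        drop(Q[Fr, Up, drop = FALSE] %*% rep(C, length(Up)))
      } else {
        numeric(length(Fr))
      }
      rhs <- c(rep(1, length(Fr)) - upper_term, -C * sum(y[Up]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[Fr] <- sol[seq_along(Fr)]
      if (any(alpha[Fr] < -1e-9) || any(alpha[Fr] > C + 1e-9)) next
    } else if (abs(sum(alpha * y)) > 1e-9) {
      next
    }
    best <- max(best, dual_obj(alpha))
  }
  best
}

# Primal soft-margin objective of a trained model.
svm_primal_objective <- function(model) {
  f <- drop(model$X %*% model$w) + model$b
  0.5 * sum(model$w^2) + model$C * sum(pmax(0, 1 - model$y * f))
}

# Random small SVM instance with both classes present.
random_svm_instance <- function(n_max = 6L) {
  n <- sample(4:n_max, 1)
  y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
  X <- matrix(rnorm(2 * n), n, 2) + 0.5 * y
  list(X = X, y = y, C = sample(c(0.1, 1, 10), 1))
}

# Dense 3D convolution oracle: product-form truncated Gaussian kernel
# (radius ceil(4 sigma) per axis), zero padding, per-output-voxel kernel
# renormalization. Direct summation; independent of the package's
# separable implementation.
dense_smooth_oracle <- function(a, sigmas) {
  d <- dim(a)
  r <- ceiling(4 * sigmas)
  g <- function(x, s) exp(-x^2 / (2 * s^2))
  out <- array(0, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    num <- 0
    in_mass <- 0
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
          zz >= 1 && zz <= d[3]) {
        w <- g(dx, sigmas[1]) * g(dy, sigmas[2]) * g(dz, sigmas[3])
        num <- num + w * a[xx, yy, zz]
        in_mass <- in_mass + w  # in-grid kernel mass: per-voxel renorm
      }
    }
    out[x, y, z] <- num / in_mass
  }
  out
}

# Two-sided Fisher exact p by full hypergeometric enumeration
# (minimum-likelihood rule), for the 2x2 table [[a, b], [c, d]].
fisher_enum_oracle <- function(a, b, c_, d) {
  m <- a + c_   # first-column margin
  n_ <- b + d
  k <- a + b    # first-row margin
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small synthetic cohorts used by several test files.
strong_signal_spec <- function(seed = 42) {
  cohort_spec(grid_shape = c(16, 16, 16), n_positive = 10, n_negative = 10,
              baseline = 0.5, noise_sd = 0.05,
              effects = list(planted_effect(c(12, 8, 8), 3, "right", 0.15)),
              smooth_fwhm_mm = 3, seed = seed)
}

null_spec <- function(seed) {
  cohort_spec(grid_shape = c(12, 12, 12), n_positive = 6, n_negative = 6,
              baseline = 0.5, noise_sd = 0.05, effects = list(),
              smooth_fwhm_mm = 3, seed = seed)
}

small_grid <- function() hyper_grid(C_values = c(0.1, 1, 10),
                                    k_values = c(10L, 30L))
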