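# Independent oracles, deliberately sharing no code with the package.

# Degrees of the five uniformly placed triangular terms at points x.
oracle_term_degrees <- function(x, lo, hi) {
  p <- lo + (0:4) * (hi - lo) / 4
  sapply(1:5, function(k) {
    a <- if (k == 1) p[1] else p[k - 1]
    b <- p[k]
    cc <- if (k == 5) p[5] else p[k + 1]
    d <- numeric(length(x))
    if (b > a) {
      i <- x >= a & x <= b
      d[i] <- (x[i] - a) / (b - a)
    }
    if (cc > b) {
      j <- x > b & x <= cc
      d[j] <- (cc - x[j]) / (cc - b)
    }
    d[x == b] <- 1
    d
  })
}

# Fine-grid Mamdani centroid: each term scaled by its aggregate firing
# weight and summed; plain Riemann quotient at high resolution.
oracle_centroid <- function(weights, lo = 1, hi = 10, n = 100001L) {
  g <- seq(lo, hi, length.out = n)
  agg <- as.vector(oracle_term_degrees(g, lo, hi) %*% weights)
  sum(g * agg) / sum(agg)
}

# Closed-form normal-equations solution for simple OLS.
oracle_ols_closed <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(b0 = mean(y) - b1 * mean(x), b1 = b1)
}

# Direct SSE minimisation over a (b0, b1) parameter grid.
oracle_ols_grid <- function(x, y, b0_range, b1_range, steps = 241L) {
  b0s <- seq(b0_range[1], b0_range[2], length.out = steps)
  b1s <- seq(b1_range[1], b1_range[2], length.out = steps)
  best <- c(NA, NA)
  best_sse <- Inf
  for (b0 in b0s) {
    for (b1 in b1s) {
      sse <- sum((y - b0 - b1 * x)^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(b0, b1)
      }
    }
  }
  c(b0 = best[1], b1 = best[2])
}

# Closed-form mean of a normal truncated to [lo, hi].
oracle_truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# The 12 published if-then rules per subsystem as (row, col, consequent)
# ordinal triples, in the published numbering (rule = 5 (i-1) + j).
printed_rules <- data.frame(
  rule = c(1, 2, 3, 11, 12, 13, 14, 15, 22, 23, 24, 25),
  i    = c(1, 1, 1, 3, 3, 3, 3, 3, 5, 5, 5, 5),
  j    = c(1, 2, 3, 1, 2, 3, 4, 5, 2, 3, 4, 5),
  k    = c(1, 1, 2, 2, 3, 3, 4, 4, 4, 4, 5, 5))
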