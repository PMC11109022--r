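# Independent brute-force oracles, kept free of the package's internals.

# Naive textbook Pearson correlation from centered sums.
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# Naive per-window pairwise correlation over jointly valid frames,
# mirroring the documented missingness rules.
naive_windowed_r <- function(track_a, track_b, channel, window_len, step,
                             min_valid_fraction) {
  xa <- track_a$intensities[, channel]
  xb <- track_b$intensities[, channel]
  nf <- length(xa)
  starts <- seq(0, nf - window_len, by = step)
  vapply(starts, function(s) {
    idx <- (s + 1):(s + window_len)
    ok <- !is.na(xa[idx]) & !is.na(xb[idx])
    if (sum(ok) < max(min_valid_fraction * window_len, 3)) return(NA_real_)
    naive_pearson(xa[idx][ok], xb[idx][ok])
  }, numeric(1))
}

# Dense-grid trapezoid integration of the JZS paired-t marginal
# likelihood: same integrand family, independent quadrature.
oracle_bf_ttest <- function(differences, scale = 0.5, one_sided = TRUE,
                            n_grid = 200001) {
  n <- length(differences)
  t_stat <- mean(differences) / (sd(differences) / sqrt(n))
  df <- n - 1
  lo <- if (one_sided) 0 else -30
  grid <- seq(lo, 30, length.out = n_grid)
  prior <- dcauchy(grid, 0, scale)
  if (one_sided) prior <- prior * 2 * (grid > 0)
  lik <- suppressWarnings(dt(t_stat, df, ncp = grid * sqrt(n)))
  f <- prior * lik
  dx <- grid[2] - grid[1]
  num <- sum((f[-1] + f[-n_grid]) / 2) * dx
  num / dt(t_stat, df)
}

# Independent series evaluation of 2F1(1/2, 1/2; c; z).
oracle_hyp2f1 <- function(c_par, z, max_k = 5000) {
  total <- 0
  log_term <- 0
  for (k in 0:max_k) {
    total <- total + exp(log_term)
    log_term <- log_term + 2 * log(0.5 + k) - log(c_par + k) -
      log(k + 1) + log(z)
    if (exp(log_term) < total * 1e-16) break
  }
  total
}

# Exact sampling density of Pearson r given rho (linear scale).
oracle_dr <- function(r, rho, n) {
  (n - 2) * gamma(n - 1) * (1 - rho^2)^((n - 1) / 2) *
    (1 - r^2)^((n - 4) / 2) /
    (sqrt(2 * pi) * gamma(n - 0.5) * (1 - rho * r)^(n - 1.5)) *
    oracle_hyp2f1(n - 0.5, (rho * r + 1) / 2)
}

# Dense-grid trapezoid BF for a correlation under the stretched
# Beta(1/width, 1/width) prior on rho.
oracle_bf_correlation <- function(r, n, width = 0.5, one_sided = TRUE,
                                  n_grid = 40001) {
  alpha <- 1 / width
  lo <- if (one_sided) 1e-8 else -1 + 1e-8
  grid <- seq(lo, 1 - 1e-8, length.out = n_grid)
  prior <- dbeta((grid + 1) / 2, alpha, alpha) / 2
  if (one_sided) prior <- prior * 2
  f <- prior * vapply(grid, function(p) oracle_dr(r, p, n), numeric(1))
  dx <- grid[2] - grid[1]
  num <- sum((f[-1] + f[-n_grid]) / 2) * dx
  num / oracle_dr(r, 0, n)
}
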