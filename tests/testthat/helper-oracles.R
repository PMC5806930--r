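# Shared oracles and fixtures, all computed in code at test time.

# Stationary autocovariance sequence of a VAR(1) z_t = A z_{t-1} + e_t with
# innovation covariance Sigma, via the discrete Lyapunov equation.
# Returns list Gamma[[h+1]] = Cov(z_t, z_{t-h}), h = 0..max_lag.
var1_autocov <- function(A, Sigma, max_lag = 10L) {
  d <- nrow(A)
  P <- matrix(solve(diag(d * d) - kronecker(A, A), as.vector(Sigma)), d)
  gam <- vector("list", max_lag + 1L)
  gam[[1L]] <- P
  for (h in seq_len(max_lag)) gam[[h + 1L]] <- A %*% gam[[h]]
  gam
}

# Population Granger causality x (index ix) -> y (index iy) at a finite AR
# order p, from the Yule-Walker projections implied by the autocovariances.
population_gc <- function(A, Sigma, p, ix = 1L, iy = 2L) {
  gam <- var1_autocov(A, Sigma, p)
  gyy <- function(h) gam[[abs(h) + 1L]][iy, iy]
  gxx <- function(h) gam[[abs(h) + 1L]][ix, ix]
  # Cov(y_t, x_{t-h}) = gam[[h+1]][iy, ix] for h >= 0
  gyx <- function(h) if (h >= 0) gam[[h + 1L]][iy, ix] else gam[[-h + 1L]][ix, iy]
  R <- outer(1:p, 1:p, Vectorize(function(i, j) gyy(i - j)))
  r <- vapply(1:p, function(h) gyy(h), 1.0)
  s2_red <- gyy(0) - drop(crossprod(r, solve(R, r)))
  Rf <- matrix(0, 2 * p, 2 * p)
  for (i in 1:p) for (j in 1:p) {
    Rf[i, j] <- gyy(i - j)
    Rf[p + i, p + j] <- gxx(i - j)
    # Cov(y_{t-i}, x_{t-j}) = Cov(y_t, x_{t-(j-i)})
    Rf[i, p + j] <- gyx(j - i)
    Rf[p + j, i] <- Rf[i, p + j]
  }
  rf <- c(vapply(1:p, function(h) gyy(h), 1.0),
          vapply(1:p, function(h) gyx(h), 1.0))
  s2_full <- gyy(0) - drop(crossprod(rf, solve(Rf, rf)))
  log(s2_red / s2_full)
}

# Simulate the bivariate VAR(1) used in the estimator-oracle tests, with a
# burn-in, returning standardized columns (x = driver, y = driven).
sim_var1_pair <- function(A, seed, n = 2000L, burn = 300L) {
  set.seed(seed)
  nt <- n + burn
  z <- matrix(0, nt, 2)
  e <- matrix(rnorm(nt * 2), nt, 2)
  for (t in 2:nt) z[t, ] <- A %*% z[t - 1, ] + e[t, ]
  z <- z[burn + seq_len(n), ]
  list(x = as.numeric(scale(z[, 1])), y = as.numeric(scale(z[, 2])))
}

# Stationary covariance of a small VAR(p) via its companion form (Lyapunov).
var_stationary_cov <- function(A_list, sigma2 = 1) {
  p <- length(A_list); N <- ncol(A_list[[1L]])
  comp <- matrix(0, N * p, N * p)
  for (l in seq_len(p)) comp[seq_len(N), (l - 1L) * N + seq_len(N)] <- A_list[[l]]
  if (p > 1L)
    comp[N + seq_len(N * (p - 1L)), seq_len(N * (p - 1L))] <- diag(N * (p - 1L))
  Q <- matrix(0, N * p, N * p)
  Q[seq_len(N), seq_len(N)] <- diag(sigma2, N)
  P <- matrix(solve(diag((N * p)^2) - kronecker(comp, comp), as.vector(Q)), N * p)
  P[seq_len(N), seq_len(N)]
}

# Power-iteration oracle for the damped PageRank fixed point.
pagerank_power <- function(P, v, alpha, tol = 1e-14, max_iter = 100000L) {
  a <- rep(1 / length(v), length(v))
  for (i in seq_len(max_iter)) {
    a_new <- alpha * (P %*% a) + (1 - alpha) * v
    a_new <- a_new / sum(a_new)
    if (max(abs(a_new - a)) < tol) return(as.numeric(a_new))
    a <- a_new
  }
  as.numeric(a)
}

# Compact planted-source session for integration tests.
make_planted_session <- function(seed, n_rows = 6, n_cols = 6, gain = 3,
                                 hub = NULL, hub_strength = 0.5,
                                 duration = 1300,
                                 seizures = list(c(300, 360), c(700, 760),
                                                 c(1100, 1160)),
                                 source = "3C") {
  g <- grid_layout(n_rows, n_cols)
  C <- default_rest_coupling(g)
  if (!is.null(hub)) {
    co <- grid_coords(g, g$labels)
    h <- match(hub, g$labels)
    nb <- which(abs(co[, 1] - co[h, 1]) + abs(co[, 2] - co[h, 2]) == 1)
    C[h, nb] <- hub_strength
  }
  cfg <- sim_config(n_rows, n_cols, fs = 500, duration = duration,
                    rest_coupling = C, source_node = source,
                    source_gain = gain, seizure_intervals = seizures,
                    seed = seed)
  simulate_session(cfg)
}
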