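# Pairwise causal estimators (GC and k-NN DI) and graph assembly.

A_pair <- rbind(c(0.5, 0), c(0.4, 0.5))     # x drives y with coefficient 0.4
A_strong <- rbind(c(0.5, 0), c(0.8, 0.3))   # strong coupling for direction tests

test_that("both estimators are near zero for independent channels", {
  gc <- vapply(1:100, function(sd) {
    set.seed(sd); estimate_gc_pair(rnorm(2000), rnorm(2000))
  }, 1.0)
  expect_lt(mean(gc), 0.01)
  di <- vapply(1:100, function(sd) {
    set.seed(sd + 500); estimate_di_pair(rnorm(2000), rnorm(2000))
  }, 1.0)
  expect_lt(mean(di), 0.02)
})

test_that("GC is directional and dominated by the true direction", {
  set.seed(60)
  x <- rnorm(1500)
  y <- c(0, x[-1500]) + rnorm(1500, sd = 0.05)
  y <- as.numeric(scale(y)); x <- as.numeric(scale(x))
  expect_gt(estimate_gc_pair(x, y), 10 * max(estimate_gc_pair(y, x), 0.01))
})

test_that("DI prefers the true direction on planted asymmetry", {
  wins <- vapply(1:100, function(sd) {
    z <- sim_var1_pair(A_strong, seed = sd + 900, n = 1000)
    estimate_di_pair(z$x, z$y) > estimate_di_pair(z$y, z$x)
  }, TRUE)
  expect_gte(sum(wins), 95)
})

test_that("GC is invariant to per-channel affine rescaling", {
  z <- sim_var1_pair(A_pair, seed = 1)
  g0 <- estimate_gc_pair(z$x, z$y)
  g1 <- estimate_gc_pair(2.5 * z$x - 7, 0.3 * z$y + 11)
  expect_lt(abs(g0 - g1), 1e-8)
})

test_that("DI is robust to strictly monotone transformations", {
  # the estimate on exp-transformed channels stays within two standard
  # errors (the estimator's own seed-to-seed sd) of the untransformed one
  est <- t(vapply(1:20, function(sd) {
    set.seed(sd)
    nt <- 2300
    z <- matrix(0, nt, 2); e <- matrix(rnorm(nt * 2), nt, 2)
    for (t in 2:nt) z[t, ] <- A_pair %*% z[t - 1, ] + e[t, ]
    z <- z[301:nt, ]
    p <- estimator_params("DI", clip_negative = FALSE)
    c(raw = estimate_di_pair(scale(z[, 1])[, 1], scale(z[, 2])[, 1], p),
      tr = estimate_di_pair(scale(exp(z[, 1]))[, 1], scale(exp(z[, 2]))[, 1], p))
  }, c(raw = 1.0, tr = 1.0)))
  expect_lt(abs(mean(est[, "tr"]) - mean(est[, "raw"])), 2 * sd(est[, "raw"]))
})

test_that("null estimates concentrate toward zero as T grows", {
  # consistency in T shows when the conditional-MI average runs over all
  # embedded points, not a fixed center subsample
  pfull <- function(n) estimator_params("DI", n_centers = n)
  m_short <- mean(vapply(1:20, function(sd) {
    set.seed(sd); estimate_di_pair(rnorm(1000), rnorm(1000), pfull(1000L))
  }, 1.0))
  m_long <- mean(vapply(1:20, function(sd) {
    set.seed(sd); estimate_di_pair(rnorm(4000), rnorm(4000), pfull(4000L))
  }, 1.0))
  expect_lt(m_long, m_short)
  g_short <- mean(vapply(1:20, function(sd) {
    set.seed(sd); estimate_gc_pair(rnorm(1000), rnorm(1000))
  }, 1.0))
  g_long <- mean(vapply(1:20, function(sd) {
    set.seed(sd); estimate_gc_pair(rnorm(4000), rnorm(4000))
  }, 1.0))
  expect_lt(g_long, g_short)
})

test_that("gc_order = 'auto' resolves a sensible BIC order", {
  z <- sim_var1_pair(A_pair, seed = 3, n = 4000)
  p <- estimator_params("GC", gc_order = "auto")
  g_auto <- estimate_gc_pair(z$x, z$y, p)
  expect_gt(g_auto, 0.05)
  ord <- ictalrank:::resolve_gc_order(matrix(z$y, ncol = 1), "auto")
  expect_true(ord >= 1 && ord <= 10)
})

test_that("estimate_graph covers all ordered pairs deterministically", {
  set.seed(12)
  b <- standardize(ecog_block(matrix(rnorm(600 * 3), ncol = 3,
                                     dimnames = list(NULL, c("1A", "1B", "1C"))),
                              200, 0, "ictal"))
  for (meas in c("DI", "GC")) {
    p <- estimator_params(meas)
    g1 <- estimate_graph(b, p)
    g2 <- estimate_graph(b, p)
    expect_identical(g1$weights, g2$weights)
    expect_true(all(diag(g1$weights) == 0))
    expect_true(all(g1$weights >= 0))
    # permutation equivariance
    perm <- c(3, 1, 2)
    bp <- ecog_block(b$data[, perm], 200, 0, "ictal")
    gp <- estimate_graph(bp, p)
    expect_equal(gp$weights, g1$weights[perm, perm], tolerance = 1e-12)
  }
})

test_that("independent-noise graphs are near-null", {
  set.seed(13)
  b <- standardize(ecog_block(matrix(rnorm(2000 * 3), ncol = 3), 200, 0, "rest"))
  g <- estimate_graph(b, estimator_params("GC"))
  expect_lt(max(g$weights), 0.05)
})

test_that("the planted source has the largest outgoing flow", {
  ok <- vapply(1:10, function(sd) {
    ses <- make_planted_session(sd + 40, duration = 400,
                                seizures = list(c(100, 160), c(220, 280),
                                                c(340, 400)))
    gs <- lapply(extract_ictal_blocks(ses), function(b)
      estimate_graph(standardize(band_limit(b)), estimator_params("DI")))
    G <- average_graphs(gs)
    which.max(rowSums(G$weights)) == match("3C", G$labels)
  }, TRUE)
  expect_gte(sum(ok), 9)
})

test_that("graph averaging is the element-wise mean", {
  W <- matrix(c(0, 1, 2, 0), 2, 2)
  a <- causal_graph(W, "DI"); b <- causal_graph(3 * W, "DI")
  expect_equal(average_graphs(list(a))$weights, a$weights)
  expect_equal(average_graphs(list(a, b))$weights, unname(2 * W),
               ignore_attr = TRUE)
  expect_equal(average_graphs(list(a, a, a))$weights, a$weights)
  expect_error(average_graphs(list(a, causal_graph(W, "GC"))), "mixed measures")
  expect_error(average_graphs(list(a, causal_graph(matrix(0, 3, 3), "DI"))),
               "mixed shapes")
})

test_that("graphs round-trip through labelled TSV", {
  set.seed(2)
  W <- matrix(runif(9), 3, 3); diag(W) <- 0
  dimnames(W) <- list(c("1A", "1B", "1C"), c("1A", "1B", "1C"))
  g <- causal_graph(W, "DI")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  back <- read_graph_tsv(path, "DI")
  expect_equal(back$weights, g$weights, tolerance = 1e-12)
  expect_equal(back$labels, g$labels)
})
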