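test_that("hard thresholding keeps large-magnitude entries and nests monotonically", {
  set.seed(1)
  S <- sample_covariance(matrix(rnorm(200), 20, 10))
  full <- hard_threshold(S, 0)
  expect_equal(graph_stats(full$graph)$n_edges, choose(10, 2))
  expect_equal(graph_stats(hard_threshold(S, max(abs(S)))$graph)$n_edges, 0L)

  # recovery of a 3-node star when the threshold separates the two levels
  ms <- correlation_from_graph(make_hub_graph(3, 1), w = 0.7, eps = 0.2)
  d_mid <- (abs(ms$C[2, 3]) + min(abs(ms$C[1, 2]), abs(ms$C[1, 3]))) / 2
  rec <- hard_threshold(ms$C, d_mid)
  expect_identical(rec$graph$adjacency, make_hub_graph(3, 1)$adjacency)

  # monotone nesting along increasing thresholds
  prev <- NULL
  for (d in seq(0, 0.8, by = 0.1)) {
    e <- hard_threshold(S, d)$graph$adjacency
    if (!is.null(prev)) expect_true(all(e <= prev))
    prev <- e
  }
})

test_that("scale-free scan fits exact power laws perfectly and flags degenerate fits", {
  # fabricate a graph whose degree histogram follows P(k) ~ k^-2 exactly at
  # k = 1, 2, 4 (counts 48, 12, 3): 3 four-leaf stars, 12 three-node chains,
  # 6 disjoint edges over p = 63 nodes
  p <- 63
  A <- matrix(0, p, p)
  add_edge <- function(i, j) { A[i, j] <<- 1; A[j, i] <<- 1 }
  idx <- 1
  for (st in 1:3) { for (l in 1:4) add_edge(idx, idx + l); idx <- idx + 5 }
  for (ch in 1:12) { add_edge(idx, idx + 1); add_edge(idx + 1, idx + 2)
    idx <- idx + 3 }
  for (e in 1:6) { add_edge(idx, idx + 1); idx <- idx + 2 }
  stopifnot(idx == p + 1)
  scan <- scale_free_scan(A, grid = 0.5)
  expect_equal(scan$n_bins, 3L)
  expect_equal(scan$R2, 1, tolerance = 1e-10)
  expect_equal(scan$gamma_hat, 2, tolerance = 1e-10)

  # regular graph: a single occupied bin, fit undefined
  ring <- make_chain_graph(10)$adjacency
  ring[1, 10] <- ring[10, 1] <- 1
  scan_reg <- scale_free_scan(ring, grid = 0.5)
  expect_true(is.na(scan_reg$R2))

  # true scale-free adjacency: positive exponent and good fit
  ok <- 0
  for (s in 1:20) {
    g <- make_scale_free_graph(500, seed = s)
    sc <- scale_free_scan(g$adjacency, grid = 0.5)
    expect_gt(sc$gamma_hat, 0)
    if (sc$R2 > 0.8) ok <- ok + 1
  }
  expect_gte(ok, 15)
})

test_that("scale-free threshold selection prefers sparse well-fitting graphs", {
  scan <- data.frame(d = c(0.2, 0.4, 0.6),
                     R2 = c(0.5, 0.9, 0.95),
                     gamma_hat = c(1, 2, -1),
                     b_hat = 0, mean_degree = c(5, 2, 1), n_bins = c(6, 5, 4))
  expect_equal(select_threshold_scale_free(scan), 0.4)  # only passing fit
  scan$gamma_hat[3] <- 1
  expect_equal(select_threshold_scale_free(scan), 0.6)  # lowest mean degree
  scan$R2 <- c(0.2, 0.3, 0.4)
  expect_error(select_threshold_scale_free(scan), "0.4")
})

test_that("covariance lasso solves the unpenalized and dominant-penalty limits", {
  set.seed(3)
  X <- matrix(rnorm(50 * 6), 50, 6)
  S <- sample_covariance(X)
  fit0 <- covariance_lasso(S, 0)
  expect_equal(fit0$estimate, S, tolerance = 1e-4)   # MLE at lambda = 0

  fit_big <- covariance_lasso(S, 50)
  off <- fit_big$estimate; diag(off) <- 0
  expect_equal(max(abs(off)), 0, tolerance = 1e-8)   # diagonal estimate
  expect_equal(diag(fit_big$estimate), diag(S), tolerance = 1e-3)

  # MM objective is monotonically non-increasing
  m <- correlation_from_graph(make_chain_graph(12), 1, 0.1)
  Xs <- sample_data(m, 40, seed = 2)
  fit <- covariance_lasso(sample_covariance(Xs), 0.2)
  expect_true(all(diff(fit$meta$objective) <= 1e-10))
})

test_that("covariance lasso recovers star support at large n", {
  m <- correlation_from_graph(make_hub_graph(3, 1), w = 1, eps = 0.2)
  hits <- 0
  for (s in 1:30) {
    X <- sample_data(m, 500, seed = s)
    fit <- covariance_lasso(sample_covariance(X), 0.05)
    if (all(fit$graph$adjacency[1, 2:3] == 1)) hits <- hits + 1
  }
  expect_gte(hits, 27)
})

test_that("cross-validated covariance lasso penalty is reproducible and interior", {
  m <- correlation_from_graph(make_chain_graph(20), 1, 0.1)
  X <- sample_data(m, 24, seed = 5)
  grid <- c(0.5, 2, 5)
  cv1 <- cv_covariance_lasso(X, grid, K = 4, seed = 11)
  cv2 <- cv_covariance_lasso(X, grid, K = 4, seed = 11)
  expect_identical(cv1$cv, cv2$cv)
  expect_true(cv1$lambda %in% grid)
  expect_equal(cv_covariance_lasso(X, 1.5, K = 4, seed = 1)$lambda, 1.5)
  expect_error(cv_covariance_lasso(X[1:5, ], grid, K = 4), "fold")
})

test_that("lasso regression satisfies its KKT conditions under the 1/n objective", {
  set.seed(7)
  n <- 60; q <- 8
  Z <- matrix(rnorm(n * q), n, q)
  beta_true <- c(2, -1, 0, 0, 0.5, 0, 0, 0)
  y <- Z %*% beta_true + rnorm(n)

  b0 <- lasso_regression(y, Z, 0)
  expect_equal(b0, qr.coef(qr(Z), y), tolerance = 1e-8, ignore_attr = TRUE)

  lam <- 0.4
  b <- lasso_regression(y, Z, lam)
  grad <- as.numeric(2 / n * crossprod(Z, y - Z %*% b))
  expect_true(all(abs(grad[b != 0]) - lam < 1e-6))
  expect_true(all(abs(grad) <= lam + 1e-6))

  # lambda above lambda_max forces the zero solution
  lam_max <- max(abs(2 / n * crossprod(Z, y)))
  expect_true(all(lasso_regression(y, Z, lam_max * 1.01) == 0))

  # orthonormal design: closed-form soft thresholding
  Q <- qr.Q(qr(matrix(rnorm(n * q), n, q))) * sqrt(n)   # Z'Z/n = I
  yq <- Q %*% beta_true + rnorm(n)
  for (lam in c(0.2, 0.8)) {
    b_hat <- lasso_regression(yq, Q, lam)
    zty <- as.numeric(crossprod(Q, yq)) / n
    b_oracle <- sign(zty) * pmax(abs(zty) - lam / 2, 0)
    expect_equal(b_hat, b_oracle, tolerance = 1e-6)
  }

  # weighted penalty: KKT with per-coefficient scaling, Inf excludes
  w <- c(0.5, 1, 2, 1, 0.1, 1, Inf, 1)
  bw <- lasso_regression(y, Z, lam, weights = w)
  expect_equal(bw[7], 0)
  gradw <- as.numeric(2 / n * crossprod(Z, y - Z %*% bw))
  act <- which(bw != 0)
  expect_true(all(abs(abs(gradw[act]) - lam * w[act]) < 1e-6))
})

test_that("nodewise lasso estimates Theta ratios and obeys the AND/OR containment", {
  # consistency: beta^i_j ~ Theta_ij / Theta_ii at large n
  g <- make_chain_graph(8)
  Theta <- diag(8) - 0.4 * g$adjacency
  m <- covariance_from_concentration(concentration_model(Theta))
  X <- sample_data(m, 2e4, seed = 3)       # rows ~ N(0, C)
  fit <- nodewise_lasso(X, 0, rule = "AND")
  B <- fit$meta$coef
  ThetaC <- solve(m$C)                     # precision of the sampled scale
  for (i in 1:8) {
    for (j in setdiff(1:8, i)) {
      target <- -ThetaC[i, j] / ThetaC[i, i]
      if (abs(target) > 1e-8)
        expect_equal(B[i, j], target, tolerance = 0.08)
    }
  }

  Xs <- sample_data(m, 40, seed = 9)
  lam_max <- max(vapply(1:8, function(i)
    max(abs(2 / 40 * crossprod(Xs[, -i], Xs[, i]))), numeric(1)))
  expect_equal(graph_stats(nodewise_lasso(Xs, lam_max * 1.05)$graph)$n_edges, 0L)

  for (lam in c(0.05, 0.2, 0.5)) {
    and_g <- nodewise_lasso(Xs, lam, rule = "AND")$graph$adjacency
    or_g <- nodewise_lasso(Xs, lam, rule = "OR")$graph$adjacency
    expect_true(all(and_g <= or_g))
  }
})

test_that("graphical lasso satisfies its stationarity conditions and stays PD", {
  # S = I: diagonal solution with entries 1/(1 + lambda)
  fit_id <- graphical_lasso(diag(5), 0.3)
  expect_equal(fit_id$estimate, diag(1 / 1.3, 5), tolerance = 1e-6)

  set.seed(4)
  for (s in 1:10) {
    p <- 8
    m <- correlation_from_graph(make_scale_free_graph(p, seed = s), 1, 0.2)
    X <- sample_data(m, 40, seed = s)
    S <- sample_covariance(X)
    lam <- 0.1
    fit <- graphical_lasso(S, lam, tol = 1e-7)
    Theta <- fit$estimate
    ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # KKT: W - S = lam * sign(Theta) on the active set, |W - S| <= lam off it
    W <- solve(Theta)
    G <- W - S
    expect_true(all(abs(G[Theta != 0] -
                          lam * sign(Theta)[Theta != 0]) < 5e-3))
    expect_true(all(abs(G) <= lam + 5e-3))
    expect_true(fit$meta$converged)
  }

  # very large penalty: diagonal estimate
  S <- sample_covariance(matrix(rnorm(200), 20, 10))
  fit_big <- graphical_lasso(S, 10 * max(abs(S)))
  off <- fit_big$estimate; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
})

test_that("adaptive lasso is a sparsification of its first stage", {
  m <- correlation_from_graph(make_chain_graph(15), 2, 0.1)
  for (s in 1:3) {
    X <- sample_data(m, 30, seed = s)
    fit <- adaptive_lasso(X, K = 5, rule = "AND", seed = s)
    B2 <- fit$meta$coef
    B1 <- fit$meta$stage1$meta$coef
    # zero first-stage coefficients stay zero
    expect_true(all(B2[B1 == 0] == 0))
    # the adaptive graph is nested in the stage-1 graph
    expect_true(all(fit$graph$adjacency <= fit$meta$stage1$graph$adjacency))
    # and sparser (or equal) overall
    expect_lte(graph_stats(fit$graph)$n_edges,
               graph_stats(fit$meta$stage1$graph)$n_edges)
  }
})
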