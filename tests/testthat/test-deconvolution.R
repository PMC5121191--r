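test_that("deconvolution inverts the transitive-closure relation exactly", {
  expect_equal(deconvolve(observation_matrix(matrix(0, 4, 4))), matrix(0, 4, 4))

  for (s in 1:20) {
    A <- random_structure(7, radius = 0.7, seed = s)
    SigM <- A %*% solve(diag(7) - A)      # full closure, nonzero diagonal
    V <- diag(SigM)
    obs <- observation_matrix(SigM - diag(V))
    # adapted deconvolution recovers A exactly
    expect_equal(deconvolve_adapted(obs, V), A, tolerance = 1e-10)
    # zero patterns of plain and adapted deconvolution coincide
    plain <- deconvolve(obs, 1)
    adapt <- deconvolve_adapted(obs, V)
    expect_identical(abs(plain) > 1e-8 & upper.tri(plain),
                     abs(adapt) > 1e-8 & upper.tri(adapt))
  }
})

test_that("V = 0 reduces adapted deconvolution to the plain transform", {
  set.seed(5)
  M <- matrix(rnorm(25), 5, 5); M <- (M + t(M)) / 2; diag(M) <- 0
  M <- M * 0.2
  obs <- observation_matrix(M)
  expect_equal(deconvolve_adapted(obs, rep(0, 5)), deconvolve(obs, 1),
               tolerance = 1e-12)
})

test_that("singular deconvolution inputs raise a rank error", {
  # constructed singularity: I + alpha*Sigma_M with alpha = -1/lambda_min
  set.seed(2)
  M <- matrix(rnorm(16), 4, 4); M <- (M + t(M)) / 2; diag(M) <- 0
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  alpha_bad <- -1 / lam[1]
  expect_error(deconvolve(observation_matrix(M), alpha_bad), "singular")
})

test_that("chain observation matrices follow the product-form weights", {
  obs <- chain_observation(4, theta = 0.3, alpha = 1)
  k <- abs(outer(1:4, 1:4, "-"))
  expect_equal(unclass(obs), ifelse(k == 0, 0, 0.3^k), tolerance = 1e-12)
  expect_equal(unclass(chain_observation(5, 0, 1)), matrix(0, 5, 5))

  # second solutions: s_1 = alpha theta^2, s_2 = alpha^2 theta^3
  obs2 <- chain_observation(4, theta = 0.3, alpha = 1.4)
  expect_equal(obs2[1, 3], 1.4 * 0.09, tolerance = 1e-12)
  expect_equal(obs2[1, 4], 1.4^2 * 0.027, tolerance = 1e-12)
  expect_error(chain_observation(4, 0.8, 1.5), "alpha")
})

test_that("KMS matrix has the closed-form tridiagonal inverse", {
  # p=4, alpha*theta = 0.5: W = 4/3, diag (4/3, 5/3, 5/3, 4/3), off -2/3
  B <- kms_matrix(4, 0.5, 1)
  Binv <- kms_inverse(4, 0.5, 1)
  expect_equal(diag(Binv), c(4 / 3, 5 / 3, 5 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(Binv[1, 2], -2 / 3, tolerance = 1e-12)
  expect_equal(B %*% Binv, diag(4), tolerance = 1e-10)

  expect_equal(kms_matrix(3, 0, 1), diag(3))
  expect_equal(kms_inverse(3, 0, 1), diag(3))
  r <- 0.4
  expect_equal(kms_inverse(2, r, 1),
               1 / (1 - r^2) * matrix(c(1, -r, -r, 1), 2), tolerance = 1e-12)

  for (p in c(2, 5, 17, 50)) {
    for (r in c(-0.7, 0.25, 0.9)) {
      expect_equal(kms_inverse(p, r, 1), solve(kms_matrix(p, r, 1)),
                   tolerance = 1e-8)
    }
  }
})

test_that("chain deconvolution is tridiagonal with the closed-form entries", {
  At <- deconvolve_chain(6, theta = 0.3, alpha = 1)
  k <- abs(outer(1:6, 1:6, "-"))
  expect_lt(max(abs(At[k >= 2])), 1e-12)
  W <- 1 / (1 - 0.09)
  expect_equal(At[1, 2], W * 0.3, tolerance = 1e-12)
  expect_equal(At[1, 2], 0.3 / (1 - 0.09), tolerance = 1e-10)
  expect_equal(At[2, 2], -2 * W * 0.09, tolerance = 1e-12)
  expect_equal(At[1, 1], -W * 0.09, tolerance = 1e-12)
  expect_equal(deconvolve_chain(5, 0.3, 0), matrix(0, 5, 5))

  # closed form == numeric deconvolution of the chain observation model
  for (theta in c(-0.25, 0.1, 0.45)) {
    for (alpha in c(0.3, 1, 1.9)) {
      if (abs(alpha * theta) > 0.9) next
      num <- deconvolve(chain_observation(8, theta, alpha), alpha)
      expect_equal(deconvolve_chain(8, theta, alpha), num, tolerance = 1e-10)
    }
  }
})

test_that("alpha roots eliminate exactly the targeted direct edge", {
  mk_obs <- function(th, s) {
    M <- matrix(0, 4, 4)
    M[1, 2] <- M[2, 1] <- th[1]; M[2, 3] <- M[3, 2] <- th[2]
    M[3, 4] <- M[4, 3] <- th[3]
    M[1, 3] <- M[3, 1] <- s[1]; M[1, 4] <- M[4, 1] <- s[2]
    M[2, 4] <- M[4, 2] <- s[3]
    observation_matrix(M)
  }
  obs <- mk_obs(c(0.4, 0.4, 0.4), c(0.1, 0.1, 0.1))
  roots <- alpha_killing_edge(obs, edge = 1)
  expect_gt(length(roots), 0)
  # the quadratic coefficients match the closed form
  th <- c(0.4, 0.4, 0.4); s <- c(0.1, 0.1, 0.1)
  M_th <- -th[1] * th[3]^2 + th[2] * th[3] * s[2] + th[3] * s[1] * s[3]
  b_th <- th[2] * s[1] + s[2] * s[3]
  expect_equal(sort(Re(polyroot(c(th[1], -b_th, M_th)))), roots,
               tolerance = 1e-8)
  for (a in roots) {
    At <- deconvolve(obs, a)
    expect_lt(abs(At[1, 2]), 1e-8)               # targeted edge killed
    expect_gt(max(abs(c(At[2, 3], At[3, 4]))), 1e-4)  # others survive
  }
  # the same property for the other direct edges
  for (e in 2:3) {
    ij <- list(c(2, 3), c(3, 4))[[e - 1]]
    for (a in alpha_killing_edge(obs, edge = e)) {
      At <- deconvolve(obs, a)
      expect_lt(abs(At[ij[1], ij[2]]), 1e-8)
    }
  }
  # negative discriminant -> no real roots
  obs_nd <- mk_obs(c(0.6, 0.05, 0.6), c(0.02, 0.3, 0.02))
  disc <- (0.05 * 0.02 + 0.3 * 0.02)^2 -
    4 * 0.6 * (-0.6 * 0.36 + 0.05 * 0.6 * 0.3 + 0.6 * 0.02 * 0.02)
  if (disc < 0) expect_length(alpha_killing_edge(obs_nd, edge = 1), 0)
})

test_that("discriminative ratio is zero at identity and order-dependent under alpha", {
  g <- make_chain_graph(6)
  model <- correlation_from_graph(g, 1, 0.1)
  SigM <- model$C; diag(SigM) <- 0
  obs <- observation_matrix(SigM)
  for (k in 2:5)
    expect_equal(discriminative_ratio(unclass(obs), obs, g, k), 0,
                 tolerance = 1e-12)

  # exact deconvolution of a true closure: indirect averages vanish -> +Inf
  A <- 0.3 * make_chain_graph(5)$adjacency
  SigM2 <- A %*% solve(diag(5) - A)
  obs2 <- observation_matrix(SigM2 - diag(diag(SigM2)))
  At <- deconvolve_adapted(obs2, diag(SigM2))
  expect_identical(discriminative_ratio(At, obs2, make_chain_graph(5), 2), Inf)

  # alpha sweep: the effect is not uniform across orders
  alphas <- seq(0.2, 2, by = 0.2)
  rmat <- sapply(2:4, function(k)
    vapply(alphas, function(a)
      discriminative_ratio(deconvolve(obs, a), obs, g, k), numeric(1)))
  # the effect of alpha is not uniform across orders: at fixed alpha the
  # orders are discriminated differently, and for some alpha one order is
  # improved (r > 0) while another is degraded (r < 0)
  expect_gt(diff(range(rmat[length(alphas), ])), 1e-6)
  mixed <- apply(rmat, 1, function(r) min(r) < 0 && max(r) > 0)
  expect_true(any(mixed))

  expect_error(discriminative_ratio(unclass(obs), obs, g, 40), "class")
})

test_that("separable direct/indirect weights stay separable after deconvolution", {
  # separable construction: min direct > max indirect in the observation
  obs <- chain_observation(6, theta = 0.45, alpha = 1)
  g <- make_chain_graph(6)
  dm <- abs(outer(1:6, 1:6, "-"))
  up <- upper.tri(dm)
  At <- deconvolve(obs, 1)
  expect_gt(min(abs(unclass(obs)[up & dm == 1])),
            max(abs(unclass(obs)[up & dm > 1])))
  expect_gt(min(abs(At[up & dm == 1])), max(abs(At[up & dm > 1])))

  # non-separable construction stays non-separable
  M <- unclass(chain_observation(6, 0.3, 1))
  M[1, 3] <- M[3, 1] <- 0.5       # one indirect edge above the direct ones
  obs_ns <- observation_matrix(M)
  At_ns <- deconvolve(obs_ns, 1)
  expect_lt(min(abs(M[up & dm == 1])), max(abs(M[up & dm > 1])))
  expect_lt(min(abs(At_ns[up & dm == 1])), max(abs(At_ns[up & dm > 1])))
})
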