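#' Observation matrix for network deconvolution
#'
#' Validates the practical convention used throughout: a symmetric matrix
#' whose diagonal is exactly zero (the closure's self-loop weights, when
#' present, are carried separately as the diagonal matrix `V`).
#'
#' @param Sigma_M symmetric numeric matrix.
#' @return The matrix, with class `observation_matrix`.
#' @export
observation_matrix <- function(Sigma_M) {
  Sigma_M <- as.matrix(Sigma_M)
  if (max(abs(Sigma_M - t(Sigma_M))) > 1e-12)
    stop("observation matrix must be symmetric")
  if (any(diag(Sigma_M) != 0))
    stop("observation matrix must have zero diagonal")
  structure(Sigma_M, class = c("observation_matrix", "matrix"))
}

#' Network deconvolution (scaled)
#'
#' \eqn{\tilde A = \alpha \Sigma_M (I + \alpha \Sigma_M)^{-1}}; with
#' \eqn{\alpha = 1} this is the plain deconvolution transform that inverts
#' the transitive-closure relation \eqn{\Sigma_M = A (I - A)^{-1}}.  The
#' scaling \eqn{\alpha} controls convergence of the implicit series.  When
#' \eqn{\Sigma_M} is a rank-deficient sample covariance (p > n) the matrix
#' \eqn{I + \alpha\Sigma_M} can be singular and the transform fails.
#'
#' @param obs symmetric zero-diagonal observation matrix.
#' @param alpha scaling parameter.
#' @return Deconvolved p x p matrix.
#' @export
deconvolve <- function(obs, alpha = 1) {
  S <- unclass(obs)
  p <- nrow(S)
  M <- diag(p) + alpha * S
  if (rcond(M) < 1e-12)
    stop("I + alpha * Sigma_M is (near) singular; deconvolution not applicable")
  out <- t(solve(M, alpha * S))
  (out + t(out)) / 2
}

#' Exact network deconvolution with self-loop correction
#'
#' The transitive closure has nonzero diagonal (closed walks), so with the
#' zero-diagonal convention \eqn{\Sigma_M = A^* - V}, \eqn{V = diag(A^*)},
#' the exact inversion reads
#' \deqn{A = \Sigma_M (I + V + \Sigma_M)^{-1} + V (I + V + \Sigma_M)^{-1}.}
#' Its off-diagonal zero pattern coincides with [deconvolve()] at
#' \eqn{\alpha = 1}.
#'
#' @param obs symmetric zero-diagonal observation matrix.
#' @param V diagonal matrix (or vector of diagonal entries) of closure
#'   self-loop weights.
#' @return Recovered p x p matrix.
#' @export
deconvolve_adapted <- function(obs, V) {
  S <- unclass(obs)
  p <- nrow(S)
  if (is.matrix(V)) V <- diag(V)
  M <- diag(p) + diag(V, p) + S
  if (rcond(M) < 1e-12)
    stop("I + V + Sigma_M is (near) singular")
  out <- t(solve(M, S + diag(V, p)))
  (out + t(out)) / 2
}

#' Chain-graph observation matrix with product-form indirect edges
#'
#' Indirect edges of order k carry weight \eqn{S_k = \alpha^{k-1}\theta^k}
#' (direct edges \eqn{\theta}), i.e.
#' \eqn{(\Sigma_M)_{ij} = \alpha^{|i-j|-1}\theta^{|i-j|}} off the diagonal.
#' This is the weight pattern under which scaled deconvolution is exact for
#' a chain.
#'
#' @param p node count.
#' @param theta direct-edge weight, |theta| < 1.
#' @param alpha scaling parameter, |alpha * theta| < 1.
#' @return An [observation_matrix()].
#' @export
chain_observation <- function(p, theta, alpha = 1) {
  if (abs(theta) >= 1 || abs(alpha * theta) >= 1)
    stop("need |theta| < 1 and |alpha * theta| < 1")
  k <- abs(outer(seq_len(p), seq_len(p), "-"))
  S <- ifelse(k == 0, 0, alpha^(k - 1) * theta^k)
  observation_matrix(S)
}

#' Kac-Murdock-Szego matrix and its tridiagonal inverse
#'
#' \eqn{B_{ij} = (\alpha\theta)^{|i-j|}}, the symmetric Toeplitz matrix
#' arising as \eqn{I + \alpha\Sigma_M} for the chain observation model.  Its
#' inverse is tridiagonal: with \eqn{W = (1-\alpha^2\theta^2)^{-1}}, corner
#' diagonal entries W, interior diagonal \eqn{W(1+\alpha^2\theta^2)} and
#' off-diagonal \eqn{-W\alpha\theta}.
#'
#' @param p matrix size (p >= 2).
#' @param theta direct-edge weight.
#' @param alpha scaling parameter; requires |alpha * theta| < 1.
#' @return `kms_matrix` returns B; `kms_inverse` returns the closed-form
#'   inverse of B.
#' @export
kms_matrix <- function(p, theta, alpha = 1) {
  r <- alpha * theta
  if (abs(r) >= 1) stop("need |alpha * theta| < 1")
  outer(seq_len(p), seq_len(p), function(i, j) r^abs(i - j))
}

#' @rdname kms_matrix
#' @export
kms_inverse <- function(p, theta, alpha = 1) {
  r <- alpha * theta
  if (abs(r) >= 1) stop("need |alpha * theta| < 1")
  W <- 1 / (1 - r^2)
  Binv <- diag(W * (1 + r^2), p)
  Binv[1, 1] <- Binv[p, p] <- W
  idx <- seq_len(p - 1)
  Binv[cbind(idx, idx + 1)] <- -W * r
  Binv[cbind(idx + 1, idx)] <- -W * r
  Binv
}

#' Closed-form chain deconvolution
#'
#' For the chain observation model the deconvolved matrix
#' \eqn{\tilde A = \alpha \Sigma_M B^{-1}} is again tridiagonal: off-diagonal
#' \eqn{W\alpha\theta}, corner diagonal \eqn{-W\alpha^2\theta^2}, interior
#' diagonal \eqn{-2W\alpha^2\theta^2}, with
#' \eqn{W = (1-\alpha^2\theta^2)^{-1}}.  So deconvolution returns a chain
#' graph exactly when the indirect weights follow the product rule.
#'
#' @inheritParams kms_matrix
#' @return The tridiagonal p x p deconvolved matrix (closed form).
#' @export
deconvolve_chain <- function(p, theta, alpha = 1) {
  r <- alpha * theta
  if (abs(r) >= 1) stop("need |alpha * theta| < 1")
  W <- 1 / (1 - r^2)
  A <- diag(-2 * W * r^2, p)
  A[1, 1] <- A[p, p] <- -W * r^2
  idx <- seq_len(p - 1)
  A[cbind(idx, idx + 1)] <- W * r
  A[cbind(idx + 1, idx)] <- W * r
  A
}

#' Scaling parameters that eliminate a direct edge
#'
#' For a 4-node chain-structured observation matrix (direct edges
#' \eqn{\theta_1,\theta_2,\theta_3} on (1,2), (2,3), (3,4); indirect
#' \eqn{s_1 = \Sigma_{13}, s_2 = \Sigma_{14}, s_3 = \Sigma_{24}}), the values
#' of \eqn{\alpha} for which the deconvolved weight of a chosen direct edge
#' vanishes are the real roots of a quadratic; for edge (1,2):
#' \deqn{M\alpha^2 - (\theta_2 s_1 + s_2 s_3)\alpha + \theta_1 = 0,\quad
#'  M = -\theta_1\theta_3^2 + \theta_2\theta_3 s_2 + \theta_3 s_1 s_3.}
#' The deconvolved (i,j) entry is proportional to the (j,i) minor of
#' \eqn{I + \alpha\Sigma_M}, a cubic in \eqn{\alpha} with zero constant term;
#' the quadratic factor's roots are recovered exactly from the minor for any
#' of the three direct edges.
#'
#' @param obs 4 x 4 [observation_matrix()].
#' @param edge which direct edge to eliminate: 1 for (1,2), 2 for (2,3),
#'   3 for (3,4).
#' @return Numeric vector of real roots (possibly empty), sorted.
#' @export
alpha_killing_edge <- function(obs, edge = 1L) {
  S <- unclass(obs)
  if (!all(dim(S) == c(4, 4))) stop("alpha_killing_edge requires p = 4")
  ij <- switch(edge, c(1L, 2L), c(2L, 3L), c(3L, 4L))
  if (is.null(ij)) stop("edge must be 1, 2 or 3")
  i <- ij[1]; j <- ij[2]
  # minor of B(alpha) = I + alpha * S, deleting row j and column i;
  # a cubic in alpha with zero constant term: interpolate exactly.
  minor <- function(a) {
    B <- diag(4) + a * S
    det(B[-j, -i, drop = FALSE])
  }
  avals <- c(1, 2, 3)
  fvals <- vapply(avals, minor, numeric(1))
  # f(a) = c1 a + c2 a^2 + c3 a^3 (constant term 0 since the (j,i) entry of
  # the identity is 0 for i != j)
  V <- outer(avals, 1:3, "^")
  coefs <- solve(V, fvals)           # (c1, c2, c3) = (theta, -b, M)
  quad <- c(coefs[1], coefs[2], coefs[3])  # theta - b*a + M*a^2
  if (abs(quad[3]) < 1e-14) {
    if (abs(quad[2]) < 1e-14) return(numeric(0))
    root <- -quad[1] / quad[2]
    return(root)
  }
  disc <- quad[2]^2 - 4 * quad[1] * quad[3]
  if (disc < 0) return(numeric(0))
  roots <- (-quad[2] + c(-1, 1) * sqrt(disc)) / (2 * quad[3])
  sort(roots)
}

#' Discriminative ratio of network deconvolution
#'
#' Compares, on the log scale, the direct/indirect average-weight separation
#' after deconvolution with the separation in the observation matrix:
#' \deqn{r = \log\frac{\langle|\tilde A_{dir}|\rangle /
#'   \langle|\tilde A_{indir,k}|\rangle}{\langle|\Sigma_{M,dir}|\rangle /
#'   \langle|\Sigma_{M,indir,k}|\rangle},}
#' computed per indirect-edge order k (order = shortest-path distance in the
#' true graph).  Absolute weights are averaged, since deconvolved weights can
#' change sign.  Positive r means deconvolution sharpens the separation for
#' that order.  Degenerate ratios return +/-Inf sentinels.
#'
#' @param A_tilde deconvolved matrix.
#' @param obs the observation matrix that was deconvolved.
#' @param g_true true (concentration) graph.
#' @param order indirect-edge order k >= 2.
#' @return Scalar log-ratio (possibly infinite).
#' @export
discriminative_ratio <- function(A_tilde, obs, g_true, order) {
  S <- unclass(obs)
  ig <- igraph::graph_from_adjacency_matrix(abs(g_true$adjacency) > 0,
                                            mode = "undirected")
  dm <- igraph::distances(ig)
  up <- upper.tri(dm)
  dir_idx <- up & dm == 1
  ind_idx <- up & dm == order
  if (!any(ind_idx) || !any(dir_idx))
    stop("no edges of the requested class in the true graph")
  ratio <- function(dir, ind) {
    # numerically zero class averages give +/-Inf sentinels, not errors
    if (dir < 1e-12 && ind < 1e-12)
      stop("undefined ratio: zero average weights in both classes")
    if (ind < 1e-12) return(Inf)
    if (dir < 1e-12) return(0)
    dir / ind
  }
  num <- ratio(mean(abs(A_tilde[dir_idx])), mean(abs(A_tilde[ind_idx])))
  den <- ratio(mean(abs(S[dir_idx])), mean(abs(S[ind_idx])))
  log(num / den)
}
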