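#' Positive-definite matrix from a graph adjacency
#'
#' Scales the binary adjacency by `w` and shifts the diagonal so the result
#' is positive definite:
#' \deqn{\hat A = w A + \gamma I, \quad \gamma = |\min_i \lambda_i(wA)| + \epsilon.}
#' The smallest eigenvalue of the output is at least `eps`.
#'
#' @param g a [weighted_graph()].
#' @param w positive edge-weight scalar; larger `w` yields stronger
#'   correlations downstream.
#' @param eps positive jitter added to the diagonal shift.
#' @return List with `Ahat` (p x p positive-definite matrix) and `params`
#'   (`w`, `gamma`, `eps`).
#' @export
pd_from_adjacency <- function(g, w = 0.5, eps = 0.1) {
  stopifnot(w > 0, eps > 0)
  wA <- w * g$adjacency
  lmin <- min(eigen(wA, symmetric = TRUE, only.values = TRUE)$values)
  gamma <- abs(lmin) + eps
  Ahat <- wA + diag(gamma, g$p)
  list(Ahat = Ahat, params = list(w = w, gamma = gamma, eps = eps))
}

#' Covariance model (covariance, correlation and scaling)
#'
#' @param Sigma symmetric positive-definite covariance matrix.
#' @return Object of class `covariance_model` with `Sigma`, correlation `C`
#'   (unit diagonal) and diagonal scaling `Lambda` with
#'   \eqn{\Lambda_{ii} = \sqrt{\Sigma_{ii}}}, so that
#'   \eqn{C = \Lambda^{-1} \Sigma \Lambda^{-1}}.
#' @export
covariance_model <- function(Sigma) {
  Sigma <- (Sigma + t(Sigma)) / 2
  lam <- sqrt(diag(Sigma))
  if (any(lam <= 0)) stop("Sigma must have positive diagonal")
  C <- stats::cov2cor(Sigma)
  structure(list(Sigma = Sigma, C = C, Lambda = diag(lam, nrow(Sigma))),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("covariance_model: p = %d, correlation strength sigma = %.4f\n",
              nrow(x$Sigma), correlation_strength(x)))
  invisible(x)
}

#' Correlation model implied by a concentration-graph topology
#'
#' The synthetic-data route: the binary adjacency is made positive definite
#' with [pd_from_adjacency()], interpreted as a precision-type matrix, and
#' inverted; the resulting covariance \eqn{\Sigma = \hat A^{-1}} is rescaled
#' to the correlation matrix \eqn{C}.  The off-diagonal zero pattern of
#' \eqn{C^{-1}} equals the input edge set, so the input graph is the
#' concentration graph of the sampled data.
#'
#' @inheritParams pd_from_adjacency
#' @return A [covariance_model()]; `$params` carries (`w`, `gamma`, `eps`).
#' @export
correlation_from_graph <- function(g, w = 0.5, eps = 0.1) {
  pd <- pd_from_adjacency(g, w, eps)
  if (rcond(pd$Ahat) < 1e-14)
    stop("pd transform is numerically singular; increase eps")
  Sigma <- chol2inv(chol(pd$Ahat))
  model <- covariance_model(Sigma)
  model$params <- pd$params
  model
}

#' Correlation strength of a model
#'
#' Population standard deviation of the correlation entries,
#' \eqn{\sigma = \sqrt{\mathrm{var}(C_{ij})}}, the variance taken over all
#' \eqn{p^2} entries including the unit diagonal (divisor \eqn{p^2}).
#'
#' @param model a [covariance_model()].
#' @return Scalar \eqn{\sigma}.
#' @export
correlation_strength <- function(model) {
  C <- model$C
  sqrt(mean(C^2) - mean(C)^2)
}

#' Calibrate the edge weight for a target correlation strength
#'
#' Finds `w` such that the correlation strength of
#' `correlation_from_graph(g, w, eps)` matches `sigma_target`.  The strength
#' is monotone increasing in `w` on the search bracket for the benchmark
#' topologies, so a root bracketing search suffices.
#'
#' @param g a [weighted_graph()].
#' @param sigma_target desired correlation strength.
#' @param eps diagonal jitter, as in [pd_from_adjacency()].
#' @param tol tolerance on the achieved strength.
#' @param bracket search interval for `w`.
#' @return Calibrated scalar `w`.
#' @export
calibrate_weight <- function(g, sigma_target, eps = 0.1, tol = 0.005,
                             bracket = c(0.01, 5)) {
  f <- function(w) correlation_strength(correlation_from_graph(g, w, eps)) -
    sigma_target
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo > tol || fhi < -tol)
    stop(sprintf(
      "sigma_target %.3f outside achievable range [%.4f, %.4f] on bracket",
      sigma_target, flo + sigma_target, fhi + sigma_target))
  if (flo >= -tol) return(bracket[1])
  if (fhi <= 0) return(bracket[2])
  r <- stats::uniroot(f, bracket, tol = 1e-6)
  w <- r$root
  if (abs(f(w)) > tol)
    stop("calibration did not reach the requested tolerance")
  w
}

#' Sample Gaussian data from a correlation model
#'
#' Factorizes \eqn{C = U^T U} (upper-triangular Cholesky factor) and returns
#' \eqn{X = R U} where `R` is n x p with i.i.d. standard normal entries, so
#' the rows of `X` are i.i.d. \eqn{N(0, C)}.
#'
#' @param model a [covariance_model()].
#' @param n sample size.
#' @param seed RNG seed.
#' @return n x p numeric matrix.
#' @export
sample_data <- function(model, n, seed = 1L) {
  C <- model$C
  U <- tryCatch(chol(C), error = function(e)
    stop("correlation matrix is not positive definite: ", conditionMessage(e)))
  set.seed(seed)
  p <- ncol(C)
  R <- matrix(stats::rnorm(n * p), n, p)
  R %*% U
}

#' Sample covariance matrix
#'
#' \eqn{S = X^T X / n} (divisor n, no mean centering: the sampling model has
#' known zero mean).  Set `center = TRUE` to subtract column means first for
#' real data.
#'
#' @param X n x p data matrix.
#' @param center subtract column means before forming the Gram matrix.
#' @return p x p symmetric positive semidefinite matrix.
#' @export
sample_covariance <- function(X, center = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 1)
  if (center) X <- sweep(X, 2, colMeans(X))
  crossprod(X) / n
}

#' Sample correlation matrix
#'
#' Unit-diagonal rescaling of [sample_covariance()]; the scale on which the
#' benchmark thresholds covariance-graph edges (thresholds live in [0, 1]).
#'
#' @inheritParams sample_covariance
#' @return p x p symmetric correlation matrix.
#' @export
sample_correlation <- function(X, center = FALSE) {
  R <- stats::cov2cor(sample_covariance(X, center))
  (R + t(R)) / 2
}
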