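#' Concentration model (precision matrix and its structure decomposition)
#'
#' Decomposes a positive-definite precision matrix as
#' \eqn{\Theta = D (I - A) D} with \eqn{D_{ii} = \sqrt{\Theta_{ii}}} and a
#' symmetric zero-diagonal structure matrix `A`.  The partial correlation
#' matrix is \eqn{\rho = I + A}, i.e.
#' \eqn{\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}} off the
#' diagonal.
#'
#' @param Theta symmetric positive-definite precision matrix.
#' @return Object of class `concentration_model` with `Theta`, `D`, `A`,
#'   `rho`.
#' @export
concentration_model <- function(Theta) {
  Theta <- (Theta + t(Theta)) / 2
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Theta must be positive definite")
  d <- sqrt(diag(Theta))
  A <- diag(nrow(Theta)) - Theta / tcrossprod(d)
  diag(A) <- 0
  structure(list(Theta = Theta, D = diag(d, nrow(Theta)), A = A,
                 rho = diag(nrow(Theta)) + A),
            class = "concentration_model")
}

spectral_radius <- function(A) {
  max(abs(eigen(A, only.values = TRUE)$values))
}

closure_result <- function(A_star, converged = TRUE, terms_used = NA_integer_) {
  structure(list(A_star = A_star, converged = converged,
                 terms_used = terms_used),
            class = "closure_result")
}

#' @export
print.closure_result <- function(x, ...) {
  cat(sprintf("closure_result: p = %d, converged = %s, terms_used = %s\n",
              nrow(x$A_star), x$converged, x$terms_used))
  invisible(x)
}

#' Transitive closure by Neumann series
#'
#' Sums the matrix power series \eqn{A^* = \sum_{m \ge 1} A^m}, which
#' converges when the spectral radius of `A` is below one and then equals
#' \eqn{(I - A)^{-1} - I}.  Entry \eqn{(i,j)} of \eqn{A^m} accumulates the
#' products of edge weights over all walks of length m from i to j, so the
#' limit weights every pair connected by a path; diagonal entries pick up
#' closed walks and are generally nonzero.
#'
#' @param A symmetric zero-diagonal structure matrix.
#' @param tol truncate when the added term's largest absolute entry falls
#'   below `tol`.
#' @param max_terms cap on the number of summed powers.
#' @return A `closure_result` with `A_star`, `converged`, `terms_used`.
#' @export
neumann_closure <- function(A, tol = 1e-12, max_terms = 10000L) {
  sr <- spectral_radius(A)
  if (sr >= 1 - 1e-9)
    stop(sprintf("Neumann series diverges: spectral radius %.6f >= 1", sr))
  acc <- A
  term <- A
  m <- 1L
  converged <- FALSE
  while (m < max_terms) {
    term <- term %*% A
    m <- m + 1L
    acc <- acc + term
    if (max(abs(term)) < tol) {
      converged <- TRUE
      break
    }
  }
  closure_result(acc, converged, m)
}

#' Exact transitive closure
#'
#' \eqn{A^* = A (I - A)^{-1} = (I - A)^{-1} - I} by a direct linear solve;
#' coincides with the Neumann series limit when the series converges.
#'
#' @param A structure matrix with `I - A` invertible.
#' @return A `closure_result`.
#' @export
closure_exact <- function(A) {
  p <- nrow(A)
  IA <- diag(p) - A
  if (rcond(IA) < 1e-14) stop("I - A is numerically singular")
  closure_result(A %*% solve(IA), TRUE, NA_integer_)
}

#' Covariance model from a concentration model
#'
#' \eqn{\Sigma = D^{-1} (I + A^*) D^{-1} = \Theta^{-1}}: the covariance is
#' the transitive closure of the concentration-graph structure, rescaled.
#' Both routes are computed and must agree within 1e-10 (relative to the
#' largest entry).
#'
#' @param model a [concentration_model()].
#' @return A [covariance_model()].
#' @export
covariance_from_concentration <- function(model) {
  dinv <- 1 / diag(model$D)
  A_star <- closure_exact(model$A)$A_star
  Sigma <- (diag(nrow(model$A)) + A_star) * tcrossprod(dinv)
  Sigma_inv_route <- chol2inv(chol(model$Theta))
  if (max(abs(Sigma - Sigma_inv_route)) > 1e-10 * max(1, max(abs(Sigma))))
    stop("closure route and direct inversion disagree")
  covariance_model(Sigma)
}

#' Closed-form transitive closure of a star graph
#'
#' For a star with hub `k` and \eqn{c = 1 - \sum_l A_{kl} A_{lk}}:
#' \eqn{A^*_{ij} = A_{ik} A_{kj} / c} for leaves \eqn{i, j \ne k},
#' \eqn{A^*_{ik} = A_{ik} / c} and \eqn{A^*_{kk} = 1/c - 1}.
#'
#' @param A structure matrix of a star (all edges incident to `k`).
#' @param k hub index.
#' @return A `closure_result`.
#' @export
star_closure <- function(A, k) {
  p <- nrow(A)
  off_hub <- A[-k, -k, drop = FALSE]
  if (any(off_hub != 0))
    stop("A is not a star centered at k: leaf-leaf edges present")
  c0 <- 1 - sum(A[k, ] * A[, k])
  if (c0 <= 0)
    stop("star closure diverges: c = 1 - sum_l A_kl A_lk <= 0")
  As <- outer(A[, k], A[k, ]) / c0
  As[k, ] <- A[k, ] / c0
  As[, k] <- A[, k] / c0
  As[k, k] <- 1 / c0 - 1
  diag_leaves <- setdiff(seq_len(p), k)
  # leaf self-loops: walks leaf -> hub -> leaf
  for (i in diag_leaves) As[i, i] <- A[i, k] * A[k, i] / c0
  closure_result(As, TRUE, NA_integer_)
}

#' Minimal transitive closure
#'
#' Adds an edge (i, j) for every pair connected by a path and weights it by
#' the sum, over all minimal-length (shortest) paths, of the product of edge
#' weights along the path.  For trees the shortest path is unique, so the
#' weight is a single product.  Existing edges are length-1 paths: their
#' weight becomes the sum over all shortest (i.e. direct) connections.
#'
#' @param g a [weighted_graph()].
#' @param node_limit refuse components larger than this (path enumeration).
#' @return A [weighted_graph()] carrying the closure weights.
#' @export
minimal_transitive_closure <- function(g, node_limit = 500L) {
  A <- g$adjacency
  ig <- igraph::graph_from_adjacency_matrix(abs(A) > 0, mode = "undirected")
  comp <- igraph::components(ig)
  if (max(comp$csize) > node_limit)
    stop("component larger than node_limit; enumeration refused")
  p <- g$p
  Tw <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = i, to = (i + 1):p))
    for (path in sp$vpaths) {
      v <- as.integer(path)
      if (length(v) < 2) next
      j <- v[length(v)]
      wprod <- prod(A[cbind(v[-length(v)], v[-1])])
      Tw[i, j] <- Tw[i, j] + wprod
      Tw[j, i] <- Tw[i, j]
    }
  }
  weighted_graph(Tw)
}

#' Verify the correlation product rule on a tree
#'
#' For a tree-structured concentration graph, the correlation of any
#' non-adjacent pair equals the product of correlations along the unique
#' connecting path (the covariance graph is the minimal transitive closure of
#' the concentration graph weighted by correlations).  Reports the residuals
#' \eqn{C_{ij} - \prod_{\mathrm{path}} C_{kl}} over all non-adjacent pairs.
#'
#' @param model a [covariance_model()] generated from `g`.
#' @param g tree (or forest) [weighted_graph()] of direct edges.
#' @return List with `max_residual`, and a data.frame `pairs` of residuals.
#' @export
verify_product_rule <- function(model, g) {
  A <- g$adjacency
  ig <- igraph::graph_from_adjacency_matrix(abs(A) > 0, mode = "undirected")
  n_edges <- igraph::ecount(ig)
  n_comp <- igraph::count_components(ig)
  if (n_edges != g$p - n_comp)
    stop("graph contains cycles; the product rule applies to trees")
  C <- model$C
  p <- g$p
  rows <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (A[i, j] != 0) next
      sp <- suppressWarnings(igraph::shortest_paths(ig, i, j))$vpath[[1]]
      v <- as.integer(sp)
      prod_c <- if (length(v) < 2) 0 else
        prod(C[cbind(v[-length(v)], v[-1])])
      rows[[length(rows) + 1]] <-
        data.frame(i = i, j = j, C_ij = C[i, j], path_product = prod_c,
                   residual = C[i, j] - prod_c)
    }
  }
  pairs <- do.call(rbind, rows)
  list(max_residual = if (is.null(pairs)) 0 else max(abs(pairs$residual)),
       pairs = pairs)
}

#' Maximum-likelihood covariance completion for the 3-node chain
#'
#' For p = 3 with the conditional-independence constraint
#' \eqn{\Theta_{13} = 0}, the maximum-likelihood covariance estimate keeps
#' every entry of the sample covariance except the constrained one, which is
#' completed as \eqn{\hat\Sigma_{13} = s_{12} s_{23} / s_{22}}; the inverse
#' of the completed matrix then has a zero (1,3) entry.
#'
#' @param S 3 x 3 nonsingular sample covariance matrix.
#' @return A [covariance_model()] of the completed estimate.
#' @export
mle_completion_3node <- function(S) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(3, 3))) stop("mle_completion_3node requires p = 3")
  if (S[2, 2] == 0) stop("s22 must be nonzero")
  if (abs(det(S)) < 1e-14) stop("S is singular")
  Sh <- S
  Sh[1, 3] <- Sh[3, 1] <- S[1, 2] * S[2, 3] / S[2, 2]
  covariance_model(Sh)
}
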