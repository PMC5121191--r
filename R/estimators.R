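#' Estimate record
#'
#' Common return type of the five graph estimators: the numeric estimate
#' (covariance, precision or coefficient-weight matrix), its binary support
#' graph, the tuning parameter and solver diagnostics.
#'
#' @param method tag: one of `thresh_cov`, `cov_lasso`, `nodewise`,
#'   `glasso`, `adaptive`.
#' @param estimate p x p symmetric matrix.
#' @param graph [weighted_graph()] with the off-diagonal support.
#' @param param tuning parameter value (threshold or penalty).
#' @param meta list of solver diagnostics.
#' @return Object of class `estimate_record`.
#' @export
estimate_record <- function(method, estimate, graph, param, meta = list()) {
  structure(list(method = method, estimate = estimate, graph = graph,
                 param = param, meta = meta),
            class = "estimate_record")
}

#' @export
print.estimate_record <- function(x, ...) {
  st <- graph_stats(x$graph)
  cat(sprintf("estimate_record [%s]: p = %d, param = %.4g, |E| = %d\n",
              x$method, x$graph$p, x$param, st$n_edges))
  invisible(x)
}

# binary support graph of a symmetric matrix, ignoring the diagonal;
# tolerance applied after scaling to unit diagonal when the diagonal is
# positive (partial-correlation scale), else on raw entries
support_graph <- function(M, zero_tol = 1e-8) {
  d <- diag(M)
  B <- M
  if (all(d > 0)) B <- M / sqrt(tcrossprod(d))
  A <- (abs(B) > zero_tol) * 1
  diag(A) <- 0
  weighted_graph((A + t(A)) / 2)
}

#' Hard-thresholded sample covariance
#'
#' Keeps the off-diagonal entries with \eqn{|S_{ij}| > d} (absolute-value
#' convention: correlation signs are arbitrary under variable reflection)
#' and zeroes the rest; the support defines the estimated covariance graph.
#'
#' @param S sample covariance matrix.
#' @param d nonnegative threshold.
#' @return An [estimate_record()] with method `thresh_cov`.
#' @export
hard_threshold <- function(S, d) {
  stopifnot(d >= 0)
  S <- as.matrix(S)
  keep <- abs(S) > d
  diag(keep) <- TRUE
  est <- S * keep
  A <- keep * 1
  diag(A) <- 0
  estimate_record("thresh_cov", est, weighted_graph(A), d)
}

#' Scale-free fit scan over thresholds
#'
#' For each threshold d, builds the hard-thresholded graph, tabulates the
#' empirical degree distribution P(k) over positive degrees, fits the
#' power-law line \eqn{\log P(k) = -\hat\gamma \log k + \hat b} by least
#' squares and records the fit quality R^2, the exponent, the intercept and
#' the mean degree.  Thresholds with fewer than two occupied positive-degree
#' bins get `NA` fit columns.
#'
#' @param S sample covariance matrix.
#' @param grid thresholds to scan.
#' @return data.frame with columns `d`, `R2`, `gamma_hat`, `b_hat`,
#'   `mean_degree`, `n_bins`.
#' @export
scale_free_scan <- function(S, grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(grid) >= 1)
  p <- nrow(S)
  out <- lapply(grid, function(d) {
    keep <- abs(S) > d
    diag(keep) <- FALSE
    degrees <- rowSums(keep)
    tab <- table(degrees[degrees >= 1])
    k <- as.numeric(names(tab))
    Pk <- as.numeric(tab) / p
    res <- data.frame(d = d, R2 = NA_real_, gamma_hat = NA_real_,
                      b_hat = NA_real_, mean_degree = mean(degrees),
                      n_bins = length(k))
    if (length(k) >= 2) {
      fit <- stats::lm(log(Pk) ~ log(k))
      # exact power laws fit perfectly; the lm warning is expected there
      res$R2 <- suppressWarnings(summary(fit)$r.squared)
      res$gamma_hat <- -stats::coef(fit)[2]
      res$b_hat <- stats::coef(fit)[1]
    }
    res
  })
  do.call(rbind, out)
}

#' Scale-free criterion threshold selection
#'
#' Among thresholds whose degree distribution fits a power law well
#' (R^2 at least `r2_min`, and a decreasing fit, i.e. positive exponent,
#' when `require_positive_gamma`), selects the one with the lowest mean
#' degree (sparsity); ties go to the smallest threshold.
#'
#' @param scan output of [scale_free_scan()].
#' @param r2_min minimum acceptable fit R^2.
#' @param require_positive_gamma require a positive fitted exponent.
#' @param min_bins minimum number of occupied degree bins for the fit to
#'   count (a two-point fit has R^2 = 1 by construction, so near-empty
#'   graphs would otherwise always win).
#' @return Selected threshold `d`.
#' @export
select_threshold_scale_free <- function(scan, r2_min = 0.8,
                                        require_positive_gamma = TRUE,
                                        min_bins = 3L) {
  stopifnot(nrow(scan) >= 1)
  ok <- !is.na(scan$R2) & scan$R2 >= r2_min & scan$n_bins >= min_bins
  if (require_positive_gamma) ok <- ok & scan$gamma_hat > 0
  if (!any(ok))
    stop(sprintf("no threshold passes the scale-free criterion (best R2 = %.3f)",
                 max(scan$R2, na.rm = TRUE)))
  cand <- scan[ok, ]
  cand <- cand[order(cand$mean_degree, cand$d), ]
  cand$d[1]
}

# objective of the sparse covariance estimator:
# log det Sigma + tr(Sigma^{-1} S) + lambda ||P o Sigma||_1
cov_lasso_objective <- function(Sigma, S, lambda, P) {
  ch <- chol(Sigma)
  2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) + lambda * sum(abs(P * Sigma))
}

# one majorization step: minimize the convex surrogate
#   h(Sigma) = tr(Theta0 Sigma) + tr(Sigma^{-1} S) + lambda ||P o Sigma||_1
# by accelerated proximal gradient (FISTA) with backtracking on the step
# size, adaptive restart, and a positive-definite safeguard (eigenvalue
# floor) applied only when a Cholesky factorization fails
cov_lasso_inner <- function(Sigma, S, lambda, P, Theta0, inner_iter = 150L,
                            inner_tol = 1e-8, eig_floor = 1e-8) {
  smooth_val <- function(Sig) {
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf, ch = NULL))
    list(val = sum(Theta0 * Sig) + sum(chol2inv(ch) * S), ch = ch)
  }
  pd_floor <- function(Sig) {
    e <- eigen(Sig, symmetric = TRUE)
    v <- pmax(e$values, eig_floor)
    tcrossprod(e$vectors %*% diag(sqrt(v), length(v)))
  }
  h_of <- function(sv, Sig) sv + lambda * sum(abs(P * Sig))
  sv <- smooth_val(Sigma)
  h_cur <- h_of(sv$val, Sigma)
  Y <- Sigma
  X_prev <- Sigma
  t_step <- 1
  tk <- 1
  stall <- 0L
  for (it in seq_len(inner_iter)) {
    svy <- smooth_val(Y)
    if (is.null(svy$ch)) {         # momentum left the PD cone: restart
      Y <- Sigma
      tk <- 1
      svy <- smooth_val(Y)
    }
    Yinv <- chol2inv(svy$ch)
    grad <- Theta0 - Yinv %*% S %*% Yinv
    grad <- (grad + t(grad)) / 2
    repeat {
      Z <- Y - t_step * grad
      thr <- t_step * lambda * P
      Xnew <- sign(Z) * pmax(abs(Z) - thr, 0)
      Xnew <- (Xnew + t(Xnew)) / 2
      svn <- smooth_val(Xnew)
      if (is.null(svn$ch)) {
        Xnew <- pd_floor(Xnew)
        svn <- smooth_val(Xnew)
      }
      # sufficient-decrease condition for the smooth part at step t
      D <- Xnew - Y
      if (svn$val <= svy$val + sum(grad * D) + sum(D * D) / (2 * t_step) +
          1e-12 || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    h_new <- h_of(svn$val, Xnew)
    if (h_new > h_cur + 1e-12 * max(1, abs(h_cur))) {
      # objective went up under momentum: restart from the last iterate
      Y <- Sigma
      tk <- 1
      stall <- stall + 1L
      if (stall > 3L) break
      next
    }
    rel <- (h_cur - h_new) / max(1, abs(h_cur))
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Xnew + ((tk - 1) / tk_new) * (Xnew - X_prev)
    tk <- tk_new
    X_prev <- Sigma
    Sigma <- Xnew
    h_cur <- h_new
    t_step <- min(t_step * 2, 1)
    if (it > 3 && rel < inner_tol) break
  }
  Sigma
}

#' Sparse covariance estimation (covariance Lasso)
#'
#' Minimizes the penalized negative profile likelihood
#' \deqn{L(\Sigma|S) = \log\det\Sigma + tr(\Sigma^{-1} S) +
#'   \lambda_{cov} \|P \circ \Sigma\|_1}
#' over positive-definite \eqn{\Sigma}, by majorization-minimization: the
#' concave \eqn{\log\det\Sigma} term is replaced by its tangent at the
#' current iterate, and the resulting convex surrogate is minimized by
#' proximal gradient descent.  The objective is non-increasing across outer
#' iterations.  By default the penalty pattern `P` is one off the diagonal
#' and zero on it (diagonal entries are not shrunk).  When p > n, a ridge
#' `s_reg * I` is added to `S` to keep the surrogate well conditioned.
#'
#' @param S sample covariance matrix.
#' @param lambda_cov nonnegative penalty.
#' @param P penalty pattern matrix (default: ones with zero diagonal).
#' @param Sigma0 initial iterate (default: the ridged `S`, so the descent
#'   lands in the stationary point nearest the sample covariance).
#' @param s_reg ridge added to `S` when p > n; default
#'   `(1 - n/p) * mean(diag(S))`.
#' @param n sample size behind `S`.  When given, it decides the p > n ridge
#'   and puts `lambda_cov` on the scale of the full-data log-likelihood
#'   (n/2 times the profile terms): the effective entrywise penalty is
#'   `2 * lambda_cov / n`.  With `n = NULL` the penalty applies to the
#'   profile objective as written.
#' @param max_iter maximum outer (majorization) iterations.
#' @param tol relative objective-change tolerance for the outer loop.
#' @return An [estimate_record()] with method `cov_lasso`; `meta$objective`
#'   is the outer objective trajectory and `meta$converged` the flag.
#' @export
covariance_lasso <- function(S, lambda_cov, P = NULL, Sigma0 = NULL,
                             s_reg = NULL, n = NULL, max_iter = 60L,
                             tol = 1e-7) {
  stopifnot(lambda_cov >= 0)
  lambda_user <- lambda_cov
  S <- (S + t(S)) / 2
  p <- nrow(S)
  if (!is.null(n)) {
    if (p > n) {
      # fill the p - n rank-deficient directions back to the average
      # variance scale; a vanishing ridge leaves a near-singular likelihood
      # basin that swallows the solution path
      if (is.null(s_reg)) s_reg <- (1 - n / p) * mean(diag(S))
      S <- S + diag(s_reg, p)
    }
    lambda_cov <- 2 * lambda_cov / n
  }
  if (is.null(P)) {
    P <- matrix(1, p, p)
    diag(P) <- 0
  }
  # start at the (ridged) sample covariance: the wanted estimate is the
  # descent solution near S, not the global minimizer of the nonconvex
  # objective (which for strong penalties is a useless diagonal-basin point)
  if (is.null(Sigma0)) Sigma0 <- S
  Sigma <- Sigma0
  objs <- cov_lasso_objective(Sigma, S, lambda_cov, P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Theta0 <- chol2inv(chol(Sigma))
    Sigma <- cov_lasso_inner(Sigma, S, lambda_cov, P, Theta0)
    objs <- c(objs, cov_lasso_objective(Sigma, S, lambda_cov, P))
    k <- length(objs)
    if (abs(objs[k - 1] - objs[k]) < tol * max(1, abs(objs[k - 1]))) {
      converged <- TRUE
      break
    }
  }
  estimate_record("cov_lasso", Sigma, support_graph(Sigma), lambda_user,
                  meta = list(objective = objs, iterations = length(objs) - 1,
                              converged = converged,
                              lambda_effective = lambda_cov))
}

#' Cross-validated penalty for the covariance Lasso
#'
#' K-fold cross-validation on the Gaussian validation likelihood: for each
#' penalty the estimator is fit on the training folds and scored by
#' \eqn{-(\log\det\hat\Sigma_T + tr(\hat\Sigma_T^{-1} S_V))} on the held-out
#' sample covariance; the penalty maximizing the average score is returned.
#'
#' @param X n x p data matrix.
#' @param grid penalty values.
#' @param K number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param s_reg ridge used in the training fits; default
#'   `0.1 * mean(diag(S_T))`.  The ridge must be small enough that
#'   under-penalized fits still overfit visibly (that is what the validation
#'   likelihood detects, and why the curve has an interior maximum), yet
#'   large enough that the p > n training fits stay well behaved.
#' @param ... passed to [covariance_lasso()].
#' @return List with `lambda` (the maximizer) and `cv` (data.frame of
#'   per-penalty mean validation log-likelihoods).
#' @export
cv_covariance_lasso <- function(X, grid, K = 5L, seed = 1L, s_reg = NULL,
                                ...) {
  n <- nrow(X)
  stopifnot(K >= 2, n >= K)
  set.seed(seed)
  folds <- sample(rep(seq_len(K), length.out = n))
  if (min(table(folds)) < 2) stop("a fold has fewer than 2 samples")
  scores <- matrix(NA_real_, length(grid), K)
  for (k in seq_len(K)) {
    Xt <- X[folds != k, , drop = FALSE]
    Xv <- X[folds == k, , drop = FALSE]
    St <- sample_covariance(Xt)
    Sv <- sample_covariance(Xv)
    sr <- if (is.null(s_reg)) 0.1 * mean(diag(St)) else s_reg
    fit_prev <- NULL
    for (gi in order(grid, decreasing = TRUE)) {
      fit <- covariance_lasso(St, grid[gi], n = nrow(Xt), s_reg = sr,
                              Sigma0 = fit_prev, ...)
      fit_prev <- fit$estimate
      ch <- chol(fit$estimate)
      scores[gi, k] <- -(2 * sum(log(diag(ch))) + sum(chol2inv(ch) * Sv))
    }
  }
  mean_ll <- rowMeans(scores)
  list(lambda = grid[which.max(mean_ll)],
       cv = data.frame(lambda = grid, mean_loglik = mean_ll))
}

#' Lasso regression
#'
#' Minimizes \eqn{(1/n)\|y - Z\beta\|_2^2 + \lambda\|\beta\|_1} (or, with
#' per-coefficient weights \eqn{w_j}, penalty
#' \eqn{\lambda\sum_j w_j|\beta_j|}).  Solved by glmnet's coordinate
#' descent; the penalty is mapped exactly onto glmnet's
#' \eqn{(1/2n)\|\cdot\|^2} normalization, including compensation for
#' glmnet's internal rescaling of penalty factors.  Coefficients with
#' infinite weight are excluded (forced to zero).
#'
#' @param y response vector (length n).
#' @param Z n x q predictor matrix.
#' @param lambda nonnegative penalty.
#' @param weights optional nonnegative per-coefficient penalty weights
#'   (`Inf` allowed).
#' @param thresh glmnet convergence threshold.
#' @return Numeric coefficient vector of length q.
#' @export
lasso_regression <- function(y, Z, lambda, weights = NULL, thresh = 1e-12) {
  stopifnot(lambda >= 0)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  q <- ncol(Z)
  beta <- numeric(q)
  active <- seq_len(q)
  if (!is.null(weights)) {
    stopifnot(length(weights) == q, all(weights >= 0))
    active <- which(is.finite(weights))
    if (length(active) == 0) return(beta)
    Z <- Z[, active, drop = FALSE]
    weights <- weights[active]
    q <- ncol(Z)
  }
  if (lambda == 0 && q <= n) {
    beta[active] <- qr.coef(qr(Z), y)
    beta[is.na(beta)] <- 0
    return(beta)
  }
  if (q == 1) {
    # univariate closed form under the stated objective
    w <- if (is.null(weights)) 1 else weights
    zty <- sum(Z * y) / n
    zz <- sum(Z^2) / n
    beta[active] <- sign(zty) * max(abs(zty) - lambda * w / 2, 0) / zz
    return(beta)
  }
  if (is.null(weights)) {
    lam_g <- lambda / 2
    fit <- glmnet::glmnet(Z, y, lambda = lam_g, standardize = FALSE,
                          intercept = FALSE, thresh = thresh)
  } else {
    lam_g <- (lambda / 2) * sum(weights) / q
    fit <- glmnet::glmnet(Z, y, lambda = lam_g, penalty.factor = weights,
                          standardize = FALSE, intercept = FALSE,
                          thresh = thresh)
  }
  beta[active] <- as.numeric(stats::coef(fit))[-1]
  beta
}

# the smallest penalty that zeroes all coefficients under the (1/n) RSS
# objective: max_j |(2/n) z_j' y| / w_j
lasso_lambda_max <- function(y, Z, weights = NULL) {
  g <- abs(as.numeric(crossprod(Z, y))) * 2 / nrow(Z)
  if (!is.null(weights)) g <- g / weights
  max(g[is.finite(g)])
}

# fit all nodewise regressions over a decreasing lambda grid in one glmnet
# path per node; returns a list (per lambda) of p x p coefficient matrices
# with B[i, j] = beta^i_j
nodewise_path <- function(X, lambda_grid, thresh = 1e-10) {
  p <- ncol(X)
  lam_sorted <- sort(unique(lambda_grid), decreasing = TRUE)
  Bs <- lapply(seq_along(lam_sorted), function(i) matrix(0, p, p))
  for (i in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -i, drop = FALSE], X[, i],
                          lambda = lam_sorted / 2, standardize = FALSE,
                          intercept = FALSE, thresh = thresh)
    cf <- as.matrix(stats::coef(fit))[-1, , drop = FALSE]
    # glmnet may drop trailing lambdas on early exit; pad with the last fit
    got <- ncol(cf)
    for (k in seq_along(lam_sorted))
      Bs[[k]][i, -i] <- cf[, min(k, got)]
  }
  names(Bs) <- as.character(lam_sorted)
  list(lambdas = lam_sorted, B = Bs)
}

# combine a nodewise coefficient matrix into an estimate_record
nodewise_record <- function(B, lambda, rule, method = "nodewise") {
  nz <- B != 0
  keep <- if (rule == "AND") nz & t(nz) else nz | t(nz)
  diag(keep) <- FALSE
  W <- (B + t(B)) / 2 * keep
  A <- keep * 1
  estimate_record(method, W, weighted_graph(A), lambda,
                  meta = list(rule = rule, coef = B))
}

#' Nodewise regression Lasso
#'
#' Estimates the concentration graph by lasso-regressing each variable on
#' all others (\eqn{\beta^i_j = \Theta_{ij}/\Theta_{ii}} at the population
#' level) and combining the two directed supports per edge with an AND or OR
#' rule.  Edge weights are the averages of the two coefficients.
#'
#' @param X n x p data matrix.
#' @param lambda_L nonnegative penalty of the per-node lasso.
#' @param rule `"AND"` (both coefficients nonzero) or `"OR"`.
#' @return An [estimate_record()] with method `nodewise`; `meta$coef` holds
#'   the full asymmetric coefficient matrix.
#' @export
nodewise_lasso <- function(X, lambda_L, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  stopifnot(lambda_L >= 0)
  p <- ncol(X)
  B <- matrix(0, p, p)
  for (i in seq_len(p))
    B[i, -i] <- lasso_regression(X[, i], X[, -i, drop = FALSE], lambda_L)
  nodewise_record(B, lambda_L, rule)
}

#' Graphical Lasso
#'
#' Maximizes the penalized log-likelihood
#' \eqn{\log\det\Theta - tr(S\Theta) - \lambda_G\|\Theta\|_1}
#' by block coordinate descent on the covariance estimate W: each column's
#' subproblem is a lasso (recast through a Cholesky factorization and solved
#' with glmnet).  Convergence is declared when the mean absolute change of
#' the off-diagonal of W over a full sweep falls below `tol` times the mean
#' absolute off-diagonal of S.  The returned precision estimate is symmetric
#' positive definite; no AND/OR combination is needed.
#'
#' @param S sample covariance matrix.
#' @param lambda_G positive penalty (required when p > n).
#' @param max_iter maximum number of full sweeps.
#' @param tol relative W-change tolerance.
#' @param warm optional list with `W` and `B` from a previous fit at a
#'   nearby penalty (warm start along a penalty path).
#' @return An [estimate_record()] with method `glasso`; `estimate` is the
#'   precision matrix \eqn{\hat\Theta}, `meta$W` the covariance estimate,
#'   `meta$w_change` the final sweep change.
#' @export
graphical_lasso <- function(S, lambda_G, max_iter = 100L, tol = 1e-4,
                            warm = NULL) {
  S <- (S + t(S)) / 2
  p <- nrow(S)
  if (lambda_G <= 0) stop("lambda_G must be positive")
  W <- S + diag(lambda_G, p)
  Bmat <- matrix(0, p, p)   # Bmat[-j, j] = beta_j
  if (!is.null(warm)) {
    off <- !diag(p)
    W[off] <- warm$W[off]
    Bmat <- warm$B
  }
  m <- p - 1
  s_scale <- mean(abs(S[upper.tri(S)]))
  if (s_scale == 0) s_scale <- 1
  crit <- Inf
  it <- 0L
  while (it < max_iter && crit > tol * s_scale) {
    it <- it + 1L
    W_old <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      R <- chol(W11)
      yv <- backsolve(R, s12, transpose = TRUE)
      beta <- tryCatch({
        fit <- glmnet::glmnet(R, yv, lambda = lambda_G / m,
                              standardize = FALSE, intercept = FALSE,
                              thresh = 1e-10)
        as.numeric(stats::coef(fit))[-1]
      }, error = function(e) Bmat[-j, j])
      Bmat[-j, j] <- beta
      w12 <- W11 %*% beta
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    Theta <- matrix(0, p, p)
    for (j in seq_len(p)) {
      beta <- Bmat[-j, j]
      denom <- W[j, j] - sum(W[-j, j] * beta)
      Theta[j, j] <- 1 / denom
      Theta[-j, j] <- -beta / denom
    }
    Theta <- (Theta + t(Theta)) / 2
    crit <- mean(abs(W - W_old)[upper.tri(W)])
  }
  estimate_record("glasso", Theta, support_graph(Theta), lambda_G,
                  meta = list(W = W, B = Bmat, w_change = crit,
                              iterations = it,
                              converged = crit <= tol * s_scale))
}

#' Adaptive Lasso (two-stage nodewise regression)
#'
#' Stage one runs nodewise lasso regressions with per-node K-fold
#' cross-validated penalties.  Stage two re-fits each node with weights
#' \eqn{1/|\tilde\beta^i_j|} on the penalty (zero first-stage coefficients
#' are excluded, so they stay zero), the penalty again selected by
#' cross-validation.  Large first-stage coefficients are thus penalized
#' lightly and small ones heavily, which prunes false positives and yields a
#' sparser graph than plain cross-validated nodewise regression.
#'
#' @param X n x p data matrix.
#' @param K folds for both cross-validations.
#' @param rule `"AND"` or `"OR"` support combination.
#' @param seed RNG seed for fold assignment.
#' @return An [estimate_record()] with method `adaptive`; `meta$stage1` is
#'   the stage-one [estimate_record()].
#' @export
adaptive_lasso <- function(X, K = 5L, rule = c("AND", "OR"), seed = 1L) {
  rule <- match.arg(rule)
  n <- nrow(X)
  p <- ncol(X)
  set.seed(seed)
  foldid <- sample(rep(seq_len(K), length.out = n))
  B1 <- matrix(0, p, p)
  B2 <- matrix(0, p, p)
  lam1 <- lam2 <- rep(NA_real_, p)
  for (i in seq_len(p)) {
    Zi <- X[, -i, drop = FALSE]
    cv1 <- glmnet::cv.glmnet(Zi, X[, i], foldid = foldid,
                             standardize = FALSE, intercept = FALSE)
    b1 <- as.numeric(stats::coef(cv1, s = "lambda.min"))[-1]
    B1[i, -i] <- b1
    lam1[i] <- cv1$lambda.min
    if (all(b1 == 0)) next
    wts <- 1 / abs(b1)   # Inf for zero first-stage coefficients
    if (sum(is.finite(wts)) < 2) {
      # a single surviving predictor: keep the stage-1 coefficient
      B2[i, -i] <- b1
      next
    }
    cv2 <- glmnet::cv.glmnet(Zi, X[, i], foldid = foldid,
                             penalty.factor = wts, standardize = FALSE,
                             intercept = FALSE)
    B2[i, -i] <- as.numeric(stats::coef(cv2, s = "lambda.min"))[-1]
    lam2[i] <- cv2$lambda.min
  }
  rec <- nodewise_record(B2, mean(lam2, na.rm = TRUE), rule,
                         method = "adaptive")
  rec$meta$stage1 <- nodewise_record(B1, mean(lam1, na.rm = TRUE), rule)
  rec$meta$lambda_stage1 <- lam1
  rec$meta$lambda_stage2 <- lam2
  rec
}
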