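#' Confusion counts of a predicted graph against the truth
#'
#' Counts over unordered node pairs (the diagonal is never counted):
#' TP/FP/FN/TN, the rates TPR = TP/(TP+FN) and FPR = FP/(FP+TN), the
#' Euclidean distance to a perfect prediction
#' \deqn{d_E = \sqrt{(T_R - C_{pred})^2 + (T_R - T_{pred})^2}}
#' (with \eqn{T_R} true edges, \eqn{C_{pred} = TP} correctly predicted and
#' \eqn{T_{pred}} total predicted edges), and `sensitivity_paper`, the
#' precision-type ratio of correctly predicted to total predicted edges
#' (`NA` when nothing is predicted).
#'
#' @param pred predicted [weighted_graph()].
#' @param truth true [weighted_graph()].
#' @return Object of class `evaluation_record` (a list of the counts and
#'   derived quantities).
#' @export
confusion <- function(pred, truth) {
  stopifnot(pred$p == truth$p)
  up <- upper.tri(truth$adjacency)
  pe <- pred$adjacency[up] != 0
  te <- truth$adjacency[up] != 0
  TP <- sum(pe & te)
  FP <- sum(pe & !te)
  FN <- sum(!pe & te)
  TN <- sum(!pe & !te)
  T_R <- TP + FN
  T_pred <- TP + FP
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    C_pred = TP, T_pred = T_pred, T_R = T_R,
    d_E = sqrt((T_R - TP)^2 + (T_R - T_pred)^2),
    TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
    sensitivity_paper = if (T_pred > 0) TP / T_pred else NA_real_),
    class = "evaluation_record")
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat(sprintf(
    "evaluation_record: TP %d FP %d FN %d TN %d | d_E %.3f sens %.3f\n",
    x$TP, x$FP, x$FN, x$TN, x$d_E,
    ifelse(is.na(x$sensitivity_paper), NaN, x$sensitivity_paper)))
  invisible(x)
}

#' Euclidean distance of a prediction from the truth
#'
#' @param record an `evaluation_record` from [confusion()].
#' @return \eqn{d_E = \sqrt{(T_R - C_{pred})^2 + (T_R - T_{pred})^2}}.
#' @export
distance_to_truth <- function(record) {
  sqrt((record$T_R - record$C_pred)^2 + (record$T_R - record$T_pred)^2)
}

#' ROC curve from a score matrix
#'
#' Thresholds the absolute scores at each cutoff and computes (FPR, TPR)
#' against the true graph.  Cutoffs of +Inf/-Inf give the (0,0) and (1,1)
#' endpoints.
#'
#' @param scores symmetric score matrix (higher magnitude = more confident
#'   edge).
#' @param truth true [weighted_graph()].
#' @param grid cutoffs; default spans the observed score range plus the two
#'   degenerate endpoints.
#' @return data.frame with columns `cutoff`, `FPR`, `TPR`, sorted by
#'   descending cutoff (so both rates are non-decreasing).
#' @export
roc_curve <- function(scores, truth, grid = NULL) {
  up <- upper.tri(scores)
  sc <- abs(scores[up])
  te <- truth$adjacency[up] != 0
  if (is.null(grid)) grid <- c(Inf, rev(sort(unique(sc))), -Inf)
  grid <- sort(grid, decreasing = TRUE)
  out <- t(vapply(grid, function(cut) {
    pe <- sc > cut
    TP <- sum(pe & te); FP <- sum(pe & !te)
    FN <- sum(!pe & te); TN <- sum(!pe & !te)
    c(FPR = if (FP + TN > 0) FP / (FP + TN) else 0,
      TPR = if (TP + FN > 0) TP / (TP + FN) else 0)
  }, numeric(2)))
  data.frame(cutoff = grid, FPR = out[, "FPR"], TPR = out[, "TPR"])
}

# run one estimator at one parameter value; input is S or X per method
run_estimator <- function(method, input, param, n = NULL, rule = "AND") {
  switch(method,
    thresh_cov = hard_threshold(input, param),
    cov_lasso = covariance_lasso(input, param, n = n),
    nodewise = nodewise_lasso(input, param, rule = rule),
    glasso = graphical_lasso(input, param),
    stop("unknown method: ", method))
}

#' Truth-optimal tuning parameter
#'
#' Runs an estimator over a parameter grid and returns the parameter
#' minimizing the Euclidean distance \eqn{d_E} from the true graph; ties go
#' to the sparser solution (the larger threshold/penalty).
#'
#' @param method one of `"thresh_cov"`, `"cov_lasso"`, `"nodewise"`,
#'   `"glasso"`.
#' @param input the sample covariance (`thresh_cov`, `cov_lasso`, `glasso`)
#'   or the data matrix (`nodewise`).
#' @param truth true [weighted_graph()].
#' @param grid parameter grid.
#' @param n sample size (covariance-lasso ridge decision).
#' @param rule nodewise AND/OR rule.
#' @return List with `param`, `record` (the winning `evaluation_record`) and
#'   `table` (per-grid-point summary).
#' @export
optimal_parameter <- function(method, input, truth, grid, n = NULL,
                              rule = "AND") {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  recs <- vector("list", length(grid))
  if (method == "nodewise") {
    path <- nodewise_path(input, grid)
    for (k in seq_along(grid)) {
      lam <- grid[k]
      B <- path$B[[as.character(lam)]]
      recs[[k]] <- confusion(nodewise_record(B, lam, rule)$graph, truth)
    }
  } else if (method == "cov_lasso") {
    fit_prev <- NULL   # ascending penalties, warm-started from the S branch
    for (k in seq_along(grid)) {
      fit <- covariance_lasso(input, grid[k], n = n, Sigma0 = fit_prev)
      fit_prev <- fit$estimate
      recs[[k]] <- confusion(fit$graph, truth)
    }
  } else if (method == "glasso") {
    warm <- NULL   # descend from the sparse end, warm-starting each fit
    for (k in rev(seq_along(grid))) {
      fit <- graphical_lasso(input, grid[k], warm = warm)
      warm <- list(W = fit$meta$W, B = fit$meta$B)
      recs[[k]] <- confusion(fit$graph, truth)
    }
  } else {
    for (k in seq_along(grid))
      recs[[k]] <- confusion(run_estimator(method, input, grid[k], n = n,
                                           rule = rule)$graph, truth)
  }
  d <- vapply(recs, function(r) r$d_E, numeric(1))
  best <- which(d == min(d))
  best <- best[length(best)]   # ties -> larger parameter (sparser)
  tab <- data.frame(
    param = grid, d_E = d,
    TP = vapply(recs, function(r) r$TP, numeric(1)),
    T_pred = vapply(recs, function(r) r$T_pred, numeric(1)),
    sensitivity = vapply(recs, function(r) r$sensitivity_paper, numeric(1)))
  list(param = grid[best], record = recs[[best]], table = tab)
}

# random-guessing baseline: predict t_pred edges uniformly among all pairs
random_guess_record <- function(truth, t_pred, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- truth$p
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  A <- matrix(0, p, p)
  if (t_pred > 0) {
    pick <- sample(nrow(pairs), min(t_pred, nrow(pairs)))
    A[pairs[pick, , drop = FALSE]] <- 1
    A <- A + t(A)
  }
  confusion(weighted_graph(A), truth)
}

#' Resampling experiment at truth-optimal parameters
#'
#' Holds one correlation model (graph and weights) fixed, draws
#' `n_resamples` independent data sets of size `n`, runs each estimator at
#' its truth-optimal parameter (minimal \eqn{d_E} over its grid) and scores
#' it; a random-guessing baseline matched to each method's predicted edge
#' count is scored alongside (rows `random_<method>`).
#'
#' @param model a [covariance_model()].
#' @param truth true [weighted_graph()].
#' @param methods character vector among `thresh_cov`, `cov_lasso`,
#'   `nodewise`, `glasso`.
#' @param grids named list of parameter grids (one per method); missing
#'   entries get defaults from [default_grid()].
#' @param n sample size per resample.
#' @param n_resamples number of data draws.
#' @param seed master seed; resample r uses substream
#'   `seed * 100000 + r`.
#' @param rule nodewise AND/OR rule.
#' @return data.frame, one row per (resample, method or baseline).
#' @export
resample_experiment <- function(model, truth, methods = c("nodewise"),
                                grids = list(), n = 30L, n_resamples = 100L,
                                seed = 1L, rule = "AND") {
  rows <- list()
  for (r in seq_len(n_resamples)) {
    sub <- (seed * 100000 + r) %% .Machine$integer.max
    X <- sample_data(model, n, seed = sub)
    S <- sample_covariance(X)
    Rm <- sample_correlation(X)
    for (m in methods) {
      input <- switch(m, nodewise = X, thresh_cov = Rm, S)
      g <- grids[[m]]
      if (is.null(g)) g <- default_grid(m, if (m == "thresh_cov") Rm else S)
      opt <- optimal_parameter(m, input, truth, g, n = n, rule = rule)
      rec <- opt$record
      rows[[length(rows) + 1]] <- data.frame(
        resample = r, method = m, param = opt$param, TP = rec$TP,
        FP = rec$FP, FN = rec$FN, TN = rec$TN, T_pred = rec$T_pred,
        T_R = rec$T_R, d_E = rec$d_E,
        sensitivity = rec$sensitivity_paper)
      rnd <- random_guess_record(truth, rec$T_pred,
                                 seed = (sub + 77777) %% .Machine$integer.max)
      rows[[length(rows) + 1]] <- data.frame(
        resample = r, method = paste0("random_", m), param = NA_real_,
        TP = rnd$TP, FP = rnd$FP, FN = rnd$FN, TN = rnd$TN,
        T_pred = rnd$T_pred, T_R = rnd$T_R, d_E = rnd$d_E,
        sensitivity = rnd$sensitivity_paper)
    }
  }
  do.call(rbind, rows)
}

#' Default tuning grids
#'
#' Threshold grid: uniform on the observed off-diagonal magnitude range.
#' Penalty grids: log-spaced from the relevant \eqn{\lambda_{max}} scale
#' downwards.
#'
#' @param method estimator tag.
#' @param S sample covariance (used to scale the grids).
#' @param length grid length.
#' @return Numeric grid.
#' @export
default_grid <- function(method, S, length = 15L) {
  off <- abs(S[upper.tri(S)])
  switch(method,
    thresh_cov = seq(0, max(off), length.out = length + 1L)[-(length + 1L)],
    cov_lasso = exp(seq(log(0.5), log(12), length.out = max(length, 20L))),
    nodewise = exp(seq(log(2 * max(off) * 1e-3), log(2 * max(off)),
                       length.out = length)),
    glasso = exp(seq(log(max(off) * 1e-2), log(max(off)),
                     length.out = length)),
    stop("unknown method: ", method))
}

#' Direct/indirect edge-weight separability of a covariance graph
#'
#' Splits the correlation magnitudes \eqn{|C_{ij}|} into direct edges (the
#' concentration-graph edge set) and indirect covariance-graph edges (pairs
#' with nonzero correlation but no direct edge), reports both samples, the
#' overlap fraction of their ranges, and the hard threshold minimizing the
#' total misclassification between the two sets.
#'
#' @param model a [covariance_model()].
#' @param truth true (concentration) [weighted_graph()].
#' @param zero_tol correlation magnitude below which a pair is not a
#'   covariance-graph edge.
#' @return List with `direct`, `indirect` (magnitude vectors),
#'   `overlap_fraction`, `threshold`, `misclassified`.
#' @export
edge_weight_separability <- function(model, truth, zero_tol = 1e-8) {
  up <- upper.tri(model$C)
  cm <- abs(model$C[up])
  te <- truth$adjacency[up] != 0
  direct <- cm[te]
  indirect <- cm[!te & cm > zero_tol]
  if (length(indirect) == 0)
    return(list(direct = direct, indirect = indirect,
                overlap_fraction = 0, threshold = min(direct) / 2,
                misclassified = 0L, degenerate = TRUE))
  lo <- max(min(direct), min(indirect))
  hi <- min(max(direct), max(indirect))
  all_v <- sort(c(direct, indirect))
  overlap <- mean(all_v >= lo & all_v <= hi)
  if (hi < lo) overlap <- 0
  cand <- c(0, (all_v[-1] + all_v[-length(all_v)]) / 2, max(all_v) + 1)
  mis <- vapply(cand, function(d)
    sum(direct <= d) + sum(indirect > d), numeric(1))
  best <- which.min(mis)
  list(direct = direct, indirect = indirect, overlap_fraction = overlap,
       threshold = cand[best], misclassified = as.integer(mis[best]),
       degenerate = FALSE)
}
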