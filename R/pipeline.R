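#' Benchmark configuration
#'
#' Bundles and validates the constants of a reconstruction experiment:
#' graph size p = 50 and sample size n = 30 (the p > n regime), 100
#' resamples, the topology parameters, estimator grids and the master seed.
#' The resample substream for draw r is `seed * 100000 + r`, so a stored
#' config reproduces every run exactly.
#'
#' @param topology one of `"chain"`, `"cluster"`, `"scale_free"`, `"hub"`.
#' @param p node count.
#' @param n sample size.
#' @param n_resamples number of data resamples.
#' @param l blocks (cluster) or hubs (hub topology).
#' @param edge_prob within-block edge probability (cluster).
#' @param w edge weight of the positive-definite transform; ignored when
#'   `sigma_targets` is given.  `NULL` picks the experiment default: 2 for
#'   the truth-optimal topology benchmark (the saturated-recovery regime)
#'   and 0.5 for the data-driven selection protocols.
#' @param eps diagonal jitter of the transform.
#' @param sigma_targets correlation strengths to calibrate `w` against
#'   (strength sweep only).
#' @param methods estimator tags to run.
#' @param grids named list of parameter grids (defaults used when missing).
#' @param K cross-validation folds.
#' @param rule nodewise AND/OR rule.
#' @param seed master seed.
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(topology = "chain", p = 50L, n = 30L,
                             n_resamples = 100L, l = NULL,
                             edge_prob = 0.3, w = NULL, eps = 0.1,
                             sigma_targets = NULL,
                             methods = c("thresh_cov", "cov_lasso",
                                         "nodewise", "glasso"),
                             grids = list(), K = 5L, rule = "AND",
                             seed = 1L) {
  topology <- match.arg(topology,
                        c("chain", "cluster", "scale_free", "hub"))
  if (is.null(l)) l <- switch(topology, cluster = 5L, hub = 10L, NA_integer_)
  if (topology %in% c("cluster", "hub") && p %% l != 0)
    stop("config error at field 'l': must divide p")
  stopifnot(p >= 2, n >= 2, n_resamples >= 1, is.null(w) || w > 0,
            eps > 0, K >= 2)
  structure(list(topology = topology, p = p, n = n,
                 n_resamples = n_resamples, l = l, edge_prob = edge_prob,
                 w = w, eps = eps, sigma_targets = sigma_targets,
                 methods = methods, grids = grids, K = K, rule = rule,
                 seed = seed),
            class = "benchmark_config")
}

# block count for a topology at size p: the divisor of p whose block size
# is closest to the benchmark's (10 for cluster blocks, 5 for hub stars)
benchmark_l <- function(topology, p) {
  target <- switch(topology, cluster = 10, hub = 5, return(NA_integer_))
  divs <- which(p %% seq_len(p) == 0)
  divs <- divs[divs < p | p <= target]          # need blocks of >= 2 nodes
  divs <- divs[p / divs >= 2]
  as.integer(divs[which.min(abs(p / divs - target))])
}

#' Benchmark truth graph for a configuration
#'
#' Builds the topology named in the config.  The cluster topology draws
#' realizations from successive seed substreams until the edge count and
#' maximum degree land in the benchmark regime (roughly 70 edges and
#' k_max = 4 at p = 50; the window scales with the expected edge count for
#' other sizes), so the screened realization is itself reproducible from
#' the config seed.
#'
#' @param config a [benchmark_config()].
#' @return A [weighted_graph()].
#' @export
benchmark_graph <- function(config) {
  p <- config$p
  switch(config$topology,
    chain = make_chain_graph(p),
    scale_free = make_scale_free_graph(p, seed = config$seed),
    hub = make_hub_graph(p, config$l),
    cluster = {
      target <- p * (p / config$l - 1) * config$edge_prob / 2
      lo <- ceiling(target); hi <- ceiling(target * 1.07)
      kcap <- max(4, ceiling(2 * target / p) + 1)
      for (try in 0:19999) {
        g <- make_cluster_graph(p, config$l, config$edge_prob,
                                seed = (config$seed * 100000 + 90000 + try) %%
                                  .Machine$integer.max)
        st <- graph_stats(g)
        if (st$n_edges >= lo && st$n_edges <= hi && st$k_max <= kcap)
          return(g)
      }
      g   # fall back to the last draw
    })
}

# write the tidy tables of a results bundle as TSV + a JSON manifest
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    utils::write.table(bundle$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Four-topology benchmark at truth-optimal parameters
#'
#' For each requested topology: builds the graph, turns it into a
#' correlation model, resamples n-sample data sets, runs every estimator at
#' its truth-optimal parameter plus the matched random-guessing baseline,
#' and summarizes mean correct/total predicted edges and the empirical
#' \eqn{d_E} distribution.
#'
#' @param config a [benchmark_config()]; `config$topology` is ignored, use
#'   `topologies`.
#' @param topologies topologies to run.
#' @param out_dir optional directory for TSV/JSON output.
#' @return List with `results` (per-resample rows), `summary` (per topology
#'   x method means) and `manifest`.
#' @export
run_topology_benchmark <- function(config,
                                   topologies = c("chain", "cluster",
                                                  "scale_free", "hub"),
                                   out_dir = NULL) {
  w_use <- if (is.null(config$w)) 2 else config$w
  all_rows <- list()
  truths <- list()
  for (topo in topologies) {
    cfg <- config
    cfg$topology <- topo
    cfg$l <- benchmark_l(topo, config$p)
    g <- benchmark_graph(cfg)
    truths[[topo]] <- g
    model <- correlation_from_graph(g, w = w_use, eps = config$eps)
    res <- resample_experiment(model, g, methods = config$methods,
                               grids = config$grids, n = config$n,
                               n_resamples = config$n_resamples,
                               seed = config$seed, rule = config$rule)
    res$topology <- topo
    all_rows[[topo]] <- res
  }
  results <- do.call(rbind, all_rows)
  summary <- stats::aggregate(
    cbind(TP, T_pred, d_E) ~ topology + method, data = results, FUN = mean)
  names(summary)[names(summary) == "TP"] <- "mean_correct"
  names(summary)[names(summary) == "T_pred"] <- "mean_predicted"
  names(summary)[names(summary) == "d_E"] <- "mean_d_E"
  bundle <- list(
    tables = list(results = results, summary = summary),
    truths = truths,
    manifest = list(kind = "topology_benchmark", p = config$p,
                    n = config$n, n_resamples = config$n_resamples,
                    w = w_use, eps = config$eps, seed = config$seed,
                    methods = config$methods, topologies = topologies,
                    version = as.character(utils::packageVersion("covgraph"))))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Correlation-strength sweep on the chain benchmark
#'
#' For each target correlation strength \eqn{\sigma}: calibrates the edge
#' weight `w`, builds the chain model, resamples, scores each method at its
#' truth-optimal parameter and reports the sensitivity (correct/total
#' predicted) averaged over resamples, as a method x strength matrix.
#'
#' @param config a [benchmark_config()] with `sigma_targets` set.
#' @param out_dir optional output directory.
#' @return List with `results`, `sensitivity` (method x sigma matrix),
#'   `weights` (calibrated w per sigma) and `manifest`.
#' @export
run_strength_sweep <- function(config, out_dir = NULL) {
  stopifnot(!is.null(config$sigma_targets))
  g <- make_chain_graph(config$p)
  all_rows <- list()
  wcal <- numeric(0)
  for (sig in config$sigma_targets) {
    w <- calibrate_weight(g, sig, eps = config$eps)
    wcal <- c(wcal, w)
    model <- correlation_from_graph(g, w = w, eps = config$eps)
    res <- resample_experiment(model, g, methods = config$methods,
                               grids = config$grids, n = config$n,
                               n_resamples = config$n_resamples,
                               seed = config$seed, rule = config$rule)
    res$sigma_target <- sig
    res$w <- w
    all_rows[[as.character(sig)]] <- res
  }
  results <- do.call(rbind, all_rows)
  keep <- results$method %in% config$methods
  sens <- stats::aggregate(sensitivity ~ method + sigma_target,
                           data = results[keep, ], FUN = mean,
                           na.action = stats::na.omit)
  mat <- stats::xtabs(sensitivity ~ method + sigma_target, data = sens)
  bundle <- list(
    tables = list(results = results,
                  sensitivity = as.data.frame.matrix(mat)),
    sensitivity = mat,
    weights = stats::setNames(wcal, config$sigma_targets),
    manifest = list(kind = "strength_sweep", p = config$p, n = config$n,
                    n_resamples = config$n_resamples, eps = config$eps,
                    sigma_targets = config$sigma_targets,
                    calibrated_w = wcal, seed = config$seed,
                    methods = config$methods,
                    version = as.character(utils::packageVersion("covgraph"))))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Data-driven selection protocols (truth not used for tuning)
#'
#' Runs the three selection procedures that do not look at the true graph:
#' scale-free-criterion thresholding of the sample covariance, fivefold
#' cross-validation for the covariance Lasso, and cross-validated adaptive
#' Lasso.  The truth enters only afterwards, to score the selected models.
#'
#' @param config a [benchmark_config()]; its `topology` decides the graph.
#' @param protocols subset of `c("scale_free_threshold", "cov_lasso_cv",
#'   "adaptive_cv")`.
#' @param out_dir optional output directory.
#' @return List with per-protocol tables and a manifest.
#' @export
run_unknown_graph_protocol <- function(config,
                                       protocols = c("scale_free_threshold",
                                                     "cov_lasso_cv",
                                                     "adaptive_cv"),
                                       out_dir = NULL) {
  w_use <- if (is.null(config$w)) 0.5 else config$w
  g <- benchmark_graph(config)
  model <- correlation_from_graph(g, w = w_use, eps = config$eps)
  tables <- list()
  for (r in seq_len(config$n_resamples)) {
    sub <- (config$seed * 100000 + r) %% .Machine$integer.max
    X <- sample_data(model, config$n, seed = sub)
    S <- sample_covariance(X)
    Rm <- sample_correlation(X)
    if ("scale_free_threshold" %in% protocols) {
      scan <- scale_free_scan(Rm)
      d_sel <- tryCatch(select_threshold_scale_free(scan),
                        error = function(e) NA_real_)
      opt <- optimal_parameter("thresh_cov", Rm, g, scan$d)
      rec <- if (is.na(d_sel)) NULL else confusion(hard_threshold(Rm, d_sel)$graph, g)
      scan$resample <- r
      tables[["scale_free_scan"]] <- rbind(tables[["scale_free_scan"]], scan)
      tables[["scale_free_selection"]] <- rbind(
        tables[["scale_free_selection"]],
        data.frame(resample = r, d_selected = d_sel, d_optimal = opt$param,
                   TP = if (is.null(rec)) NA else rec$TP,
                   T_pred = if (is.null(rec)) NA else rec$T_pred,
                   d_E = if (is.null(rec)) NA else rec$d_E))
    }
    if ("cov_lasso_cv" %in% protocols) {
      grid <- config$grids$cov_lasso
      if (is.null(grid)) grid <- seq(0.5, 7, by = 0.5)
      cv <- cv_covariance_lasso(X, grid, K = config$K, seed = sub)
      fit <- covariance_lasso(S, cv$lambda, n = config$n,
                              s_reg = 0.1 * mean(diag(S)))
      rec <- confusion(fit$graph, g)
      cv$cv$resample <- r
      tables[["cov_lasso_cv_curve"]] <- rbind(tables[["cov_lasso_cv_curve"]], cv$cv)
      tables[["cov_lasso_cv"]] <- rbind(
        tables[["cov_lasso_cv"]],
        data.frame(resample = r, lambda_cv = cv$lambda, TP = rec$TP,
                   T_pred = rec$T_pred, d_E = rec$d_E))
    }
    if ("adaptive_cv" %in% protocols) {
      fit <- adaptive_lasso(X, K = config$K, rule = config$rule, seed = sub)
      rec <- confusion(fit$graph, g)
      rec1 <- confusion(fit$meta$stage1$graph, g)
      tables[["adaptive_cv"]] <- rbind(
        tables[["adaptive_cv"]],
        data.frame(resample = r, TP = rec$TP, T_pred = rec$T_pred,
                   d_E = rec$d_E, stage1_TP = rec1$TP,
                   stage1_T_pred = rec1$T_pred))
    }
  }
  bundle <- list(
    tables = tables, truth = g,
    manifest = list(kind = "unknown_graph_protocol",
                    topology = config$topology, p = config$p, n = config$n,
                    n_resamples = config$n_resamples, w = w_use,
                    eps = config$eps, K = config$K, seed = config$seed,
                    protocols = protocols,
                    version = as.character(utils::packageVersion("covgraph"))))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}
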