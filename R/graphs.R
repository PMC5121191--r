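#' Weighted undirected graph
#'
#' Light container for an undirected weighted graph represented by its
#' symmetric adjacency matrix with zero diagonal.  The edge set is the set of
#' unordered pairs \eqn{(i,j)}, \eqn{i<j}, with a nonzero adjacency entry.
#'
#' @param adjacency symmetric numeric matrix with zero diagonal.
#' @return An object of class `weighted_graph` with elements `p` (node count)
#'   and `adjacency`.
#' @export
weighted_graph <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-12)
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have zero diagonal")
  dimnames(adjacency) <- NULL
  structure(list(p = nrow(adjacency), adjacency = adjacency),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf("weighted_graph: p = %d, |E| = %d, k_max = %d\n",
              x$p, st$n_edges, st$k_max))
  invisible(x)
}

#' Chain (tridiagonal) graph
#'
#' Path graph 1 - 2 - ... - p, i.e. a tridiagonal binary adjacency matrix
#' with p - 1 edges and maximum degree 2.
#'
#' @param p node count, at least 2.
#' @return A binary [weighted_graph()].
#' @export
make_chain_graph <- function(p) {
  if (p < 2) stop("chain graph needs p >= 2")
  A <- matrix(0, p, p)
  idx <- seq_len(p - 1)
  A[cbind(idx, idx + 1)] <- 1
  A[cbind(idx + 1, idx)] <- 1
  weighted_graph(A)
}

#' Cluster graph
#'
#' Nodes are evenly partitioned into `l` disjoint blocks of size p/l; within
#' each block every pair is connected independently with probability
#' `edge_prob`; there are no between-block edges.  Expected edge count is
#' p (p/l - 1) edge_prob / 2.
#'
#' @param p node count.
#' @param l number of blocks; must divide `p`.
#' @param edge_prob within-block edge probability in (0, 1].
#' @param seed RNG seed for the Bernoulli draws.
#' @return A binary [weighted_graph()] with `l` components (or more, when
#'   sparse blocks disconnect internally).
#' @export
make_cluster_graph <- function(p, l, edge_prob = 0.3, seed = 1L) {
  if (p %% l != 0) stop("l must divide p")
  if (edge_prob <= 0 || edge_prob > 1)
    stop("edge_prob must be in (0, 1]")
  b <- p / l
  A <- matrix(0, p, p)
  set.seed(seed)
  for (k in seq_len(l)) {
    nodes <- ((k - 1) * b + 1):(k * b)
    for (i in seq_len(b - 1)) {
      for (j in (i + 1):b) {
        if (stats::runif(1) <= edge_prob) {
          A[nodes[i], nodes[j]] <- 1
          A[nodes[j], nodes[i]] <- 1
        }
      }
    }
  }
  weighted_graph(A)
}

#' Scale-free graph (preferential attachment)
#'
#' Barabasi-Albert growth: nodes arrive one at a time and attach `m` edges to
#' existing nodes with probability proportional to their current degree.  With
#' the default m = 1 the result is a tree with exactly p - 1 edges, so the
#' degree sequence follows a power law while the edge count matches the chain
#' and benchmark graphs.
#'
#' @param p node count, at least 2.
#' @param seed RNG seed.
#' @param m edges attached per new node (default 1).
#' @return A binary [weighted_graph()].
#' @export
make_scale_free_graph <- function(p, seed = 1L, m = 1L) {
  if (p < 2) stop("scale-free graph needs p >= 2")
  set.seed(seed)
  g <- igraph::sample_pa(p, power = 1, m = m, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  weighted_graph(A)
}

#' Hub (star) graph
#'
#' Nodes are evenly partitioned into `l` disjoint blocks; in each block the
#' first node is a hub connected to every other node of the block.  The graph
#' has p - l edges and hub degree p/l - 1.
#'
#' @param p node count.
#' @param l number of hubs; must divide `p`.
#' @return A binary [weighted_graph()].
#' @export
make_hub_graph <- function(p, l = 1L) {
  if (p %% l != 0) stop("l must divide p")
  b <- p / l
  if (b < 2) stop("blocks need at least 2 nodes")
  A <- matrix(0, p, p)
  for (k in seq_len(l)) {
    hub <- (k - 1) * b + 1
    leaves <- (hub + 1):(k * b)
    A[hub, leaves] <- 1
    A[leaves, hub] <- 1
  }
  weighted_graph(A)
}

#' Structural statistics of a graph
#'
#' @param g a [weighted_graph()].
#' @return List with `degrees` (per-node degree from the nonzero off-diagonal
#'   pattern), `k_max` and `n_edges`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  B <- g$adjacency != 0
  degrees <- rowSums(B)
  list(degrees = as.integer(degrees),
       k_max = as.integer(max(degrees)),
       n_edges = as.integer(sum(B[upper.tri(B)])))
}

#' Number of connected components
#'
#' @param g a [weighted_graph()].
#' @return Integer component count (isolated nodes count as components).
#' @export
graph_components <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(abs(g$adjacency) > 0,
                                            mode = "undirected")
  igraph::count_components(ig)
}

#' Edge list of a weighted graph
#'
#' @param g a [weighted_graph()].
#' @return data.frame with 1-based columns `node_i < node_j` and `weight`.
#' @export
graph_edges <- function(g) {
  A <- g$adjacency
  up <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  data.frame(node_i = up[, 1], node_j = up[, 2],
             weight = A[up])[order(up[, 1], up[, 2]), , drop = FALSE]
}

#' Write / read a graph as a TSV edge list
#'
#' Columns (node_i, node_j, weight), 1-based, i < j, no header.
#'
#' @param g a [weighted_graph()].
#' @param path file path.
#' @param p node count (needed on read; isolated trailing nodes are not
#'   recoverable from the edge list alone).
#' @return `read_edge_list` returns a [weighted_graph()];
#'   `write_edge_list` returns `path` invisibly.
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(graph_edges(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, p) {
  e <- utils::read.table(path, sep = "\t",
                         col.names = c("node_i", "node_j", "weight"))
  A <- matrix(0, p, p)
  A[cbind(e$node_i, e$node_j)] <- e$weight
  A[cbind(e$node_j, e$node_i)] <- e$weight
  weighted_graph(A)
}

#' Write / read a dense adjacency (or any) matrix as CSV
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_csv` returns a matrix; the writer returns `path`
#'   invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
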