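# shared fixtures, built in code

# the 3-node star with both edge weights 0.4 (hub = node 1)
star3_A <- function(a = 0.4, b = 0.4) {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- a
  A[1, 3] <- A[3, 1] <- b
  A
}

# random symmetric zero-diagonal matrix rescaled to a given spectral radius
random_structure <- function(p, radius = 0.6, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p, p)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A * radius / max(abs(eigen(A, only.values = TRUE)$values))
}

# random tree structure (uniform random attachment) with weights
random_tree_graph <- function(p, wmin = 0.1, wmax = 0.35, seed = 1) {
  set.seed(seed)
  A <- matrix(0, p, p)
  for (v in 2:p) {
    u <- sample(v - 1, 1)
    w <- stats::runif(1, wmin, wmax) * sample(c(-1, 1), 1)
    A[u, v] <- A[v, u] <- w
  }
  weighted_graph(A)
}
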