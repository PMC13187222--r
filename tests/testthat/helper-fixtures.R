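# Shared helpers: tiny response matrices, brute-force oracles.

tiny_matrix <- function(values, group = NULL, ...) {
  v <- as.matrix(values)
  if (is.null(group))
    group <- rep(c("case", "comparison"), length.out = nrow(v))
  response_matrix(v, group, ...)
}

# Weighted modularity of a partition, computed from first principles:
# Q = sum_ij (A_ij - k_i k_j / (2m)) [c_i == c_j] / (2m).
modularity_oracle <- function(adj, membership) {
  two_m <- sum(adj)
  if (two_m == 0) return(0)
  k <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / two_m) * same) / two_m
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    i <- length(prefix) + 1
    if (i > n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

max_modularity_exhaustive <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) modularity_oracle(adj, p), numeric(1)))
}

# item_network built straight from a weighted adjacency matrix (weights are
# treated as supra-threshold correlations).
net_from_adjacency <- function(adj, threshold = 0.5) {
  ids <- rownames(adj)
  if (is.null(ids)) ids <- paste0("IP", seq_len(nrow(adj)))
  corr <- adj
  dimnames(corr) <- list(ids, ids)
  diag(corr) <- 1
  build_network(corr, threshold = threshold)
}

# Random connected-ish weighted graph on n nodes with edge weights in
# (threshold, 0.95]; returns adjacency with zero diagonal.
random_weighted_graph <- function(n, p_edge = 0.5, threshold = 0.7) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p_edge) {
        w <- stats::runif(1, threshold + 0.01, 0.95)
        adj[i, j] <- adj[j, i] <- w
      }
    if (any(adj > 0)) return(adj)
  }
}

# A data matrix whose sample covariance is EXACTLY sigma (n > ncol).
exact_cov_data <- function(n, sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(sigma)
  x <- matrix(stats::rnorm(n * p), n)
  x <- scale(x, center = TRUE, scale = FALSE)
  s <- stats::cov(x)
  x <- x %*% solve(chol(s)) %*% chol(sigma)
  x
}

two_factor_spec <- function() {
  cfa_spec(list(F1 = paste0("IP", 1:12), F2 = paste0("IP", 13:18)))
}
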