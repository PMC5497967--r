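# Independent brute-force oracles used across the suite.  These deliberately
# avoid igraph and the package's own metric code paths.

# wrap a 0/1 adjacency matrix as a communication_network
adj_to_net <- function(adj) {
  dimnames(adj) <- NULL
  structure(list(adjacency = adj, density = NA_real_,
                 threshold_value = NA_real_,
                 labels = paste0("n", seq_len(nrow(adj)))),
            class = "communication_network")
}

# exhaustive local clustering: for each node, count closed neighbour pairs
brute_clustering <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    closed <- sum(apply(pairs, 2, function(p) adj[p[1], p[2]] == 1))
    closed / ncol(pairs)
  }, 0))
}

# all-pairs shortest paths by Floyd-Warshall
brute_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_path_length <- function(adj, mode = "reachable") {
  d <- brute_distances(adj)
  ut <- d[upper.tri(d)]
  if (mode == "penalized") {
    ut[is.infinite(ut)] <- nrow(adj)
    return(mean(ut))
  }
  mean(ut[is.finite(ut)])
}

# connected components by label propagation
brute_giant <- function(adj) {
  d <- brute_distances(adj)
  max(vapply(seq_len(nrow(adj)), function(i) sum(is.finite(d[i, ])), 0))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# plug-in (histogram) MI of two discrete label vectors, in nats
plugin_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  sum(ifelse(tab > 0, tab * log(tab / outer(px, py)), 0))
}

# rank-based AUC of pos scores vs neg scores (Mann-Whitney)
rank_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

# a random undirected simple graph on n nodes with edge prob p (fixed seed
# handled by caller); returned as an adjacency matrix
random_adj <- function(n, p) {
  adj <- matrix(0, n, n)
  ut <- which(upper.tri(adj))
  adj[ut] <- as.numeric(runif(length(ut)) < p)
  adj + t(adj)
}

# a small MI-matrix stand-in with prescribed values
fake_mi <- function(values) {
  labels <- paste0("ch", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, n_channels = nrow(values),
                 labels = labels, window_index = NA_integer_),
            class = "mi_matrix")
}

# correlated standard bivariate Gaussian draws
rbvn <- function(n, rho) {
  z <- matrix(rnorm(2 * n), ncol = 2)
  z %*% chol(matrix(c(1, rho, rho, 1), 2))
}
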