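as_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Build a binary communication network by density thresholding
#'
#' Ranks all n(n-1)/2 unordered channel pairs by averaged mutual information
#' (descending; ties broken deterministically by ascending row then column
#' index) and keeps the strongest `round(density * total)` pairs as edges.
#' The smallest retained MI value is recorded as the applied threshold.
#' Thresholding by connection density rather than by a fixed MI value makes
#' network topology comparable across recordings with different overall MI
#' levels.
#'
#' @param mi an `mi_matrix` (typically the window-averaged matrix).
#' @param density fraction of the strongest edges to preserve, in (0, 1].
#' @return Object of class `communication_network`: list with `adjacency`
#'   (symmetric 0/1, zero diagonal), `density`, `threshold_value` (nats)
#'   and `labels`.
#' @export
threshold_by_density <- function(mi, density) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (density <= 0 || density > 1) stop_invalid("density must be in (0, 1]")
  n <- mi$n_channels
  ut <- which(upper.tri(mi$values), arr.ind = TRUE)
  vals <- mi$values[ut]
  total <- nrow(ut)
  m <- floor(density * total + 0.5)            # half-up rounding
  ord <- order(-vals, ut[, 1], ut[, 2])
  adj <- matrix(0, n, n, dimnames = list(mi$labels, mi$labels))
  thr <- NA_real_
  if (m == 0) {
    warning("density yields zero edges; returning an empty network")
  } else {
    keep <- ord[seq_len(m)]
    adj[ut[keep, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    thr <- vals[keep[m]]
  }
  structure(list(adjacency = adj, density = density, threshold_value = thr,
                 labels = mi$labels),
            class = "communication_network")
}

#' @export
print.communication_network <- function(x, ...) {
  cat(sprintf("Communication network: %d nodes, %d edges (density %.2f, threshold %.4f nats)\n",
              nrow(x$adjacency), count_edges(x), x$density, x$threshold_value))
  invisible(x)
}

#' Number of edges in a network
#' @param net a `communication_network` (or any object with a 0/1 adjacency).
#' @return Edge count (half the adjacency sum).
#' @export
count_edges <- function(net) sum(net$adjacency) / 2

#' Average degree of a network
#' @inheritParams count_edges
#' @return `2 * edges / nodes`.
#' @export
average_degree <- function(net) 2 * count_edges(net) / nrow(net$adjacency)

#' Size of the giant component
#'
#' Node count of the largest connected subgraph; an isolated node counts as
#' a component of size 1, so an empty network has giant component 1.
#'
#' @inheritParams count_edges
#' @return Integer node count.
#' @export
giant_component_size <- function(net) {
  max(igraph::components(as_graph(net))$csize)
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (probability that
#' two neighbours of a node are themselves neighbours); nodes with degree
#' below 2 contribute 0.
#'
#' @inheritParams count_edges
#' @return Fraction in \[0, 1\].
#' @export
average_clustering <- function(net) {
  igraph::transitivity(as_graph(net), type = "localaverage",
                       isolates = "zero")
}

#' Characteristic path length
#'
#' Mean geodesic (shortest-path) distance over node pairs. Density
#' thresholding at 0.1 routinely disconnects the network, and the treatment
#' of unreachable pairs changes what the metric measures:
#' `"reachable"` averages over reachable pairs only (unreachable pairs are
#' excluded, so fragmentation can shorten L); `"giant"` restricts the
#' average to the giant component; `"penalized"` counts each unreachable
#' pair at distance `n_nodes` (one more than the longest possible geodesic),
#' so that fragmentation lengthens L and the metric behaves as a global
#' connectivity measure. The pipeline uses `"penalized"` by default (see
#' [default_config()]); the null-model normalization applies whichever mode
#' the empirical side uses, so normalized comparisons stay internally
#' consistent.
#'
#' @inheritParams count_edges
#' @param mode `"reachable"` (default), `"giant"` or `"penalized"`.
#' @return Mean geodesic distance in hops (>= 1 when any edge exists).
#' @export
characteristic_path_length <- function(net, mode = c("reachable", "giant",
                                                     "penalized")) {
  mode <- match.arg(mode)
  if (count_edges(net) == 0)
    stop(structure(class = c("afcn_undefined_metric", "error", "condition"),
                   list(message = "path length undefined: network has no edges",
                        call = sys.call())))
  g <- as_graph(net)
  if (mode == "penalized") {
    d <- igraph::distances(g)
    n <- nrow(d)
    d[is.infinite(d)] <- n
    return(mean(d[upper.tri(d)]))
  }
  if (mode == "giant") {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  igraph::mean_distance(g, unconnected = TRUE)
}

graph_to_net <- function(g, labels = NULL) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj > 0) + 0
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, density = NA_real_,
                 threshold_value = NA_real_,
                 labels = labels %||% paste0("n", seq_len(nrow(adj)))),
            class = "communication_network")
}

#' Matched Erdos-Renyi null ensemble
#'
#' Draws `ensemble_size` uniform random graphs G(n, m) with exactly the node
#' and edge counts of the empirical network (hence the same average degree)
#' and computes clustering, path length and the per-draw small-world ratio
#' with the same conventions as the empirical pipeline. The summary is used
#' to normalize empirical metrics and to express the small-world index as a
#' z-score.
#'
#' @param n_nodes,n_edges node and edge counts to match.
#' @param ensemble_size number of random graphs (default 100).
#' @param seed integer seed; fixed seed gives identical ensemble statistics.
#' @param path_mode path-length convention, see
#'   [characteristic_path_length()].
#' @return Object of class `null_ensemble`: list with `n_nodes`, `n_edges`,
#'   `ensemble_size`, `seed`, `mean_C_rand`, `sd_C_rand`, `mean_L_rand`,
#'   `sd_L_rand`, `sigma_rand_values`, `C_values`, `L_values`.
#' @export
build_null_ensemble <- function(n_nodes, n_edges, ensemble_size = 100,
                                seed = 1, path_mode = "reachable") {
  max_m <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_m)
    stop_invalid("n_edges must lie in [0, n(n-1)/2]")
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  C <- L <- numeric(ensemble_size)
  for (i in seq_len(ensemble_size)) {
    net <- graph_to_net(igraph::sample_gnm(n_nodes, n_edges))
    C[i] <- average_clustering(net)
    L[i] <- if (n_edges == 0) NA_real_ else
      characteristic_path_length(net, mode = path_mode)
  }
  mC <- mean(C); mL <- mean(L)
  sigma <- (C / mC) / (L / mL)
  structure(list(n_nodes = n_nodes, n_edges = n_edges,
                 ensemble_size = ensemble_size, seed = as.integer(seed),
                 mean_C_rand = mC, sd_C_rand = sd(C),
                 mean_L_rand = mL, sd_L_rand = sd(L),
                 sigma_rand_values = sigma, C_values = C, L_values = L),
            class = "null_ensemble")
}

check_null_match <- function(net, null) {
  if (nrow(net$adjacency) != null$n_nodes ||
      count_edges(net) != null$n_edges)
    stop_invalid("null ensemble (n = ", null$n_nodes, ", m = ", null$n_edges,
                 ") does not match the network (n = ", nrow(net$adjacency),
                 ", m = ", count_edges(net), ")")
}

#' Null-normalized clustering and path length
#'
#' @param net a `communication_network`.
#' @param null a matched `null_ensemble`.
#' @param path_mode path-length convention, see
#'   [characteristic_path_length()].
#' @return Named list `C_norm = C / mean_C_rand`,
#'   `L_norm = L / mean_L_rand`.
#' @export
normalized_metrics <- function(net, null, path_mode = "reachable") {
  check_null_match(net, null)
  if (!is.finite(null$mean_C_rand) || null$mean_C_rand == 0)
    stop(structure(class = c("afcn_undefined_normalization", "error", "condition"),
                   list(message = "null ensemble mean clustering is zero",
                        call = sys.call())))
  list(C_norm = average_clustering(net) / null$mean_C_rand,
       L_norm = characteristic_path_length(net, mode = path_mode) / null$mean_L_rand)
}

#' Small-world index and its z-score
#'
#' `sigma = C_norm / L_norm`, the ratio of null-normalized clustering to
#' null-normalized path length (> 1 indicates small-world organization).
#' The z-score locates the empirical sigma within the distribution of the
#' same ratio computed for each null-ensemble draw.
#'
#' @inheritParams normalized_metrics
#' @return Named list with `sigma` and `z` (`z` is `NA` with a warning when
#'   the null sigma distribution is degenerate).
#' @export
small_world_index <- function(net, null, path_mode = "reachable") {
  nm <- normalized_metrics(net, null, path_mode)
  sigma <- nm$C_norm / nm$L_norm
  s <- sd(null$sigma_rand_values)
  z <- if (is.na(s) || s == 0) {
    warning("null sigma distribution is degenerate; z undefined")
    NA_real_
  } else (sigma - mean(null$sigma_rand_values)) / s
  list(sigma = sigma, z = z)
}

#' All six communication-network parameters for one network
#'
#' @param net a `communication_network`.
#' @param null optional matched `null_ensemble`; when supplied, the
#'   normalized clustering, normalized path length, small-world index and
#'   its z-score are included.
#' @param path_mode path-length convention.
#' @return One-row `data.frame` with columns `n_edges`, `avg_degree`,
#'   `giant_component`, `avg_clustering`, `char_path_length`, and when a
#'   null is given `C_norm`, `L_norm`, `small_world_sigma`, `small_world_z`.
#' @export
network_metrics <- function(net, null = NULL, path_mode = "reachable") {
  m <- count_edges(net)
  out <- data.frame(
    n_edges = m,
    avg_degree = average_degree(net),
    giant_component = giant_component_size(net),
    avg_clustering = average_clustering(net),
    char_path_length = if (m > 0)
      characteristic_path_length(net, mode = path_mode) else NA_real_)
  if (!is.null(null)) {
    nm <- normalized_metrics(net, null, path_mode)
    sw <- small_world_index(net, null, path_mode)
    out$C_norm <- nm$C_norm
    out$L_norm <- nm$L_norm
    out$small_world_sigma <- sw$sigma
    out$small_world_z <- sw$z
  }
  out
}

#' Network metrics across a grid of connection densities
#'
#' Thresholds the MI matrix at each density of the grid (default 0.10 to
#' 0.30 in steps of 0.01) and computes the full parameter set against a
#' G(n, m) null ensemble matched at each density. Null seeds are derived
#' deterministically from `null_seed` and the edge count, so ensembles are
#' shared across recordings compared at the same density.
#'
#' @param mi an `mi_matrix`.
#' @param densities density grid within (0, 1].
#' @param ensemble_size random graphs per null ensemble.
#' @param null_seed base seed for the null ensembles.
#' @param path_mode path-length convention.
#' @return `data.frame`, one row per density, with `density`,
#'   `threshold_value` and the [network_metrics()] columns; per-density
#'   failures yield `NA` rows rather than aborting the sweep.
#' @export
density_sweep <- function(mi, densities = seq(0.10, 0.30, by = 0.01),
                          ensemble_size = 100, null_seed = 1,
                          path_mode = "reachable") {
  if (any(densities <= 0 | densities > 1))
    stop_invalid("densities must lie in (0, 1]")
  cache <- new.env(parent = emptyenv())
  rows <- lapply(densities, function(d) {
    tryCatch({
      net <- threshold_by_density(mi, d)
      m <- count_edges(net)
      key <- as.character(m)
      if (is.null(cache[[key]]))
        cache[[key]] <- build_null_ensemble(
          mi$n_channels, m, ensemble_size,
          seed = derive_seed(null_seed, "null", m), path_mode = path_mode)
      cbind(data.frame(density = d, threshold_value = net$threshold_value),
            network_metrics(net, cache[[key]], path_mode))
    }, error = function(e) {
      warning("density ", d, ": ", conditionMessage(e))
      data.frame(density = d, threshold_value = NA_real_, n_edges = NA_real_,
                 avg_degree = NA_real_, giant_component = NA_real_,
                 avg_clustering = NA_real_, char_path_length = NA_real_,
                 C_norm = NA_real_, L_norm = NA_real_,
                 small_world_sigma = NA_real_, small_world_z = NA_real_)
    })
  })
  do.call(rbind, rows)
}
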