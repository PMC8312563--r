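# Global and nodal graph metrics on binary undirected networks.
#
# Conventions (GRETNA-compatible):
#   * nodes of degree < 2 have clustering 0 and local-efficiency contribution 0
#   * Lp and nodal path length average finite distances only; the fraction of
#     disconnected pairs is reported alongside
#   * betweenness is unnormalized (raw unordered-pair counts)

#' All-pairs shortest-path distances
#'
#' Hop-count distances on an unweighted undirected network, computed by
#' breadth-first search from every source. Unreachable pairs are `Inf`.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @return Numeric distance matrix (0 diagonal, `Inf` for unreachable pairs).
#' @export
shortest_paths <- function(adj) {
  validate_adjacency(adj)
  storage.mode(adj) <- "integer"
  bfs_distances(adj)
}

#' Clustering coefficient
#'
#' Watts-Strogatz nodal clustering: the fraction of realized edges among a
#' node's neighbors, `2 * t_i / (k_i (k_i - 1))` with `t_i` triangles through
#' node i. Nodes with degree < 2 get 0. The global value `cp` is the
#' unweighted mean over all nodes, isolated nodes included.
#'
#' @inheritParams shortest_paths
#' @return List with `ci` (per-node) and `cp` (global mean).
#' @export
clustering_coef <- function(adj) {
  validate_adjacency(adj)
  k <- rowSums(adj)
  a <- adj * 1.0
  tri2 <- diag(a %*% a %*% a)       # = 2 * triangles through each node
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri2 / denom, 0)
  list(ci = as.numeric(ci), cp = mean(ci))
}

#' Characteristic path length
#'
#' Nodal path length `li` is the mean hop distance from node i to every node
#' it can reach; the global `lp` is the mean over all reachable ordered pairs.
#' Isolated or fully unreachable nodes have `li = NA`. The fraction of
#' disconnected (infinite-distance) ordered pairs is returned so the
#' finite-only averaging convention is always visible.
#'
#' @param dm Distance matrix from [shortest_paths()].
#' @return List with `li` (per-node, `NA` when undefined), `lp` (global, `NA`
#'   when no pair is reachable) and `disconnected_pair_fraction`.
#' @export
characteristic_path_length <- function(dm) {
  n <- nrow(dm)
  off <- dm
  diag(off) <- NA
  finite <- is.finite(off)
  li <- vapply(seq_len(n), function(i) {
    d <- off[i, ][finite[i, ]]
    if (length(d) == 0) NA_real_ else mean(d)
  }, numeric(1))
  n_pairs <- n * (n - 1)
  n_finite <- sum(finite, na.rm = TRUE)
  lp <- if (n_finite == 0) NA_real_ else mean(off[finite], na.rm = TRUE)
  list(li = li, lp = lp,
       disconnected_pair_fraction = (n_pairs - n_finite) / n_pairs)
}

#' Global and nodal efficiency
#'
#' Nodal efficiency `ei` is the mean inverse distance from node i to all other
#' nodes (unreachable pairs contribute 0); global efficiency `ge` is the mean
#' over all ordered pairs. Both lie in \[0, 1\], with 1 for a complete graph.
#'
#' @inheritParams characteristic_path_length
#' @return List with `ei` (per-node) and `ge` (global).
#' @export
global_efficiency <- function(dm) {
  n <- nrow(dm)
  inv <- 1 / dm
  diag(inv) <- NA
  ei <- rowMeans(inv, na.rm = TRUE)
  ei[is.nan(ei)] <- 0          # n = 1 edge case
  list(ei = as.numeric(ei), ge = mean(inv[!is.na(inv)]))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors; nodes with fewer than two neighbors contribute 0. The global
#' value is the mean over all nodes.
#'
#' @inheritParams shortest_paths
#' @return List with `eloc` (per-node) and `loce` (global mean).
#' @export
local_efficiency <- function(adj) {
  validate_adjacency(adj)
  n <- nrow(adj)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) >= 2) {
      sub <- adj[nb, nb, drop = FALSE]
      storage.mode(sub) <- "integer"
      eloc[i] <- global_efficiency(bfs_distances(sub))$ge
    }
  }
  list(eloc = eloc, loce = mean(eloc))
}

#' Degree centrality
#'
#' @inheritParams shortest_paths
#' @return Integer vector of node degrees.
#' @export
degree_centrality <- function(adj) {
  validate_adjacency(adj)
  as.integer(rowSums(adj))
}

#' Betweenness centrality
#'
#' Brandes' algorithm on the unweighted network: for every unordered
#' source--target pair, each intermediate node accrues the fraction of
#' geodesics passing through it. Values are left unnormalized (raw pair
#' counts); normalization cancels in the rank-based hub criteria.
#'
#' @inheritParams shortest_paths
#' @return Numeric vector of betweenness values, >= 0.
#' @export
betweenness_centrality <- function(adj) {
  validate_adjacency(adj)
  storage.mode(adj) <- "integer"
  as.numeric(brandes_betweenness(adj))
}

#' Per-node metric table
#'
#' Computes the five nodal quantities the hub criteria and group comparisons
#' need: degree `di`, nodal efficiency `ei`, betweenness `bi`, clustering
#' `ci`, and nodal path length `li`.
#'
#' @inheritParams shortest_paths
#' @param node_labels Optional character vector of node labels (defaults to
#'   the AAL-90 abbreviations when the network has 90 nodes, otherwise
#'   `"n1"..."nN"`).
#' @return A tibble with one row per node: `node`, `label`, `di`, `ei`, `bi`,
#'   `ci`, `li`.
#' @export
nodal_metrics <- function(adj, node_labels = NULL) {
  validate_adjacency(adj)
  n <- nrow(adj)
  if (is.null(node_labels)) {
    node_labels <- if (n == 90) aal90_labels()$abbrev else paste0("n", seq_len(n))
  }
  if (length(node_labels) != n) abort("`node_labels` length must match n_nodes.")
  dm <- shortest_paths(adj)
  cl <- clustering_coef(adj)
  pl <- characteristic_path_length(dm)
  ef <- global_efficiency(dm)
  tibble::tibble(
    node = seq_len(n),
    label = node_labels,
    di = degree_centrality(adj),
    ei = ef$ei,
    bi = betweenness_centrality(adj),
    ci = cl$ci,
    li = pl$li
  )
}

#' Whole-network metric summary
#'
#' Assembles the seven global parameters: clustering coefficient `cp`,
#' characteristic path length `lp`, local and global efficiency
#' `loce`/`ge`, and — when a degree-preserving null ensemble is supplied —
#' the normalized parameters `gamma` (Cp ratio), `lambda` (Lp ratio) and
#' small-worldness `sigma = gamma / lambda`.
#'
#' @inheritParams shortest_paths
#' @param ensemble Optional null ensemble from [build_ensemble()]; without it
#'   the normalized parameters are `NA`.
#' @return A one-row tibble: `cp`, `lp`, `loce`, `ge`, `gamma`, `lambda`,
#'   `sigma`, `disconnected_pair_fraction`, `n_null_lp_undefined`.
#' @export
global_metrics <- function(adj, ensemble = NULL) {
  validate_adjacency(adj)
  dm <- shortest_paths(adj)
  cl <- clustering_coef(adj)
  pl <- characteristic_path_length(dm)
  ef <- global_efficiency(dm)
  le <- local_efficiency(adj)
  norm <- if (is.null(ensemble)) {
    list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
         n_lp_undefined = NA_integer_)
  } else {
    normalized_metrics(adj, ensemble)
  }
  tibble::tibble(
    cp = cl$cp, lp = pl$lp, loce = le$loce, ge = ef$ge,
    gamma = norm$gamma, lambda = norm$lambda, sigma = norm$sigma,
    disconnected_pair_fraction = pl$disconnected_pair_fraction,
    n_null_lp_undefined = norm$n_lp_undefined
  )
}
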