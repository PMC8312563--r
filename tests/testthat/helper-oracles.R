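# Brute-force reference implementations, kept deliberately naive and
# independent of the package's computational paths.

# Floyd-Warshall all-pairs shortest paths.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Per-node clustering by explicit neighbor-pair enumeration.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(1:n, function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      links <- links + adj[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  })
}

# Global efficiency by direct inverse-distance enumeration.
oracle_global_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vals <- 1 / d[row(d) != col(d)]
  mean(vals)
}

# Local efficiency via the neighbor-subgraph definition.
oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  per <- sapply(1:n, function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
  list(per = per, global = mean(per))
}

# Betweenness by exhaustive enumeration of all geodesics (DFS over paths),
# feasible only for tiny graphs.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bc <- numeric(n)
  all_geodesics <- function(s, t) {
    paths <- list()
    walk <- function(v, path) {
      if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] == 1)) {
        if (is.finite(d[w, t]) && d[w, t] == d[v, t] - 1) walk(w, c(path, w))
      }
    }
    if (is.finite(d[s, t])) walk(s, s)
    paths
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- all_geodesics(s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) bc[v] <- bc[v] + 1 / length(paths)
    }
  }
  bc
}

# Random simple undirected graph on n nodes with edge probability p.
random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  adj[ut] <- as.integer(runif(length(ut)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# Small helper graphs.
complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L; adj
}
path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}
star_graph <- function(n_leaves) {
  adj <- matrix(0L, n_leaves + 1, n_leaves + 1)
  adj[1, -1] <- adj[-1, 1] <- 1L
  adj
}
cycle_graph <- function(n) {
  adj <- path_graph(n)
  adj[1, n] <- adj[n, 1] <- 1L
  adj
}
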