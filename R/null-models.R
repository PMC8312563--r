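# Degree-preserving null models and normalized small-world parameters.

#' Degree-preserving rewiring
#'
#' Randomizes a network by Maslov-Sneppen double-edge swaps: two edges
#' (a,b) and (c,d) are replaced by (a,d) and (c,b). A candidate swap is
#' rejected — and counted — when it would create a self-loop or a duplicate
#' edge, so the result is always a simple undirected graph with exactly the
#' input degree sequence.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal, >= 2
#'   edges.
#' @param swap_factor Number of attempted swaps per edge (default 10).
#' @param seed Optional integer seed; when supplied the rewiring is
#'   reproducible.
#' @return Rewired adjacency matrix with attributes `n_rejected` and
#'   `n_accepted` recording the swap bookkeeping.
#' @export
rewire_degree_preserving <- function(adj, swap_factor = 10, seed = NULL) {
  validate_adjacency(adj)
  m <- sum(adj) / 2
  if (m < 2) abort("Network must have at least 2 edges to rewire.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  storage.mode(adj) <- "integer"
  res <- double_edge_swap(adj, as.integer(round(swap_factor * m)))
  out <- res$adjacency
  attr(out, "n_rejected") <- res$n_rejected
  attr(out, "n_accepted") <- res$n_accepted
  out
}

#' Build a null ensemble of degree-matched random networks
#'
#' Generates `m` independent degree-preserving rewirings of a network; these
#' provide the denominators of the normalized clustering coefficient and
#' normalized path length. Member i uses seed `seed + i`, so the ensemble is
#' reproducible and each member auditable.
#'
#' @inheritParams rewire_degree_preserving
#' @param m Ensemble size (default 100).
#' @param seed Integer base seed.
#' @return An object of class `wmnet_null_ensemble`: list with `networks`,
#'   `m`, `degree_sequence`, `swap_factor`, `seed`.
#' @export
build_ensemble <- function(adj, m = 100, swap_factor = 10, seed = 1L) {
  validate_adjacency(adj)
  if (m < 1) abort("`m` must be >= 1.")
  nets <- lapply(seq_len(m), function(i) {
    rewire_degree_preserving(adj, swap_factor, seed = as.integer(seed) + i)
  })
  structure(
    list(networks = nets, m = as.integer(m),
         degree_sequence = as.integer(rowSums(adj)),
         swap_factor = swap_factor, seed = as.integer(seed)),
    class = "wmnet_null_ensemble")
}

#' @export
print.wmnet_null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<wmnet_null_ensemble> m = %d degree-preserving rewirings (%d nodes, %d edges, seed %d)\n",
    x$m, length(x$degree_sequence), sum(x$degree_sequence) %/% 2L, x$seed))
  invisible(x)
}

#' Normalized small-world parameters
#'
#' `gamma` is the network's clustering coefficient divided by the ensemble
#' mean; `lambda` is the path-length ratio; `sigma = gamma / lambda` is the
#' small-worldness index (> 1 for small-world organization). Ensemble members
#' whose path length is undefined (no reachable pair) are excluded from the
#' `lambda` denominator and counted.
#'
#' @inheritParams rewire_degree_preserving
#' @param ensemble A `wmnet_null_ensemble` built from `adj`'s degree
#'   sequence.
#' @return List with `gamma`, `lambda`, `sigma`, `n_lp_undefined`. All three
#'   are `NA` when every ensemble member has undefined path length.
#' @export
normalized_metrics <- function(adj, ensemble) {
  validate_adjacency(adj)
  stopifnot(inherits(ensemble, "wmnet_null_ensemble"))
  if (!identical(sort(as.integer(rowSums(adj))),
                 sort(ensemble$degree_sequence))) {
    abort("Ensemble degree sequence does not match the network.")
  }
  cp_real <- clustering_coef(adj)$cp
  lp_real <- characteristic_path_length(shortest_paths(adj))$lp
  null_cp <- vapply(ensemble$networks,
                    function(a) clustering_coef(a)$cp, numeric(1))
  null_lp <- vapply(ensemble$networks, function(a) {
    characteristic_path_length(bfs_distances(a))$lp
  }, numeric(1))
  n_undef <- sum(is.na(null_lp))
  if (n_undef == ensemble$m || is.na(lp_real)) {
    return(list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
                n_lp_undefined = n_undef))
  }
  gamma <- cp_real / mean(null_cp)
  lambda <- lp_real / mean(null_lp, na.rm = TRUE)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       n_lp_undefined = as.integer(n_undef))
}
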