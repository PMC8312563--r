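# Four-criterion hub identification.

# Indices of the k nodes with the best value of `x`; `decreasing = TRUE`
# selects the highest. Ties at the boundary are broken by lower node index
# (stable order of `order()`), and NA ranks worst.
top_k_nodes <- function(x, k, decreasing) {
  key <- if (decreasing) -as.numeric(x) else as.numeric(x)
  ord <- order(key, seq_along(x), na.last = TRUE)
  ord[seq_len(k)]
}

#' Four-criterion hubness scores
#'
#' Scores each node 0--4, one point per criterion met: (1) top
#' `top_fraction` of nodes by degree `di`; (2) top fraction by betweenness
#' `bi`; (3) bottom fraction by nodal clustering `ci`; (4) bottom fraction by
#' nodal path length `li`. Nodes scoring at least `score_threshold`
#' (default 2) are flagged as putative hubs. `k = ceiling(top_fraction * n)`
#' nodes are selected per criterion; boundary ties are broken by lower node
#' index and an undefined `li` ranks last (never "lowest path length").
#'
#' @param nodal A nodal metric table from [nodal_metrics()] (columns `node`,
#'   `label`, `di`, `bi`, `ci`, `li`).
#' @param top_fraction Fraction of nodes selected per criterion, in (0, 1).
#' @param score_threshold Minimum score for hub status (default 2).
#' @return The input tibble with added columns `high_di`, `high_bi`,
#'   `low_ci`, `low_li` (logical), `score` (0--4) and `is_hub`.
#' @export
hubness_scores <- function(nodal, top_fraction = 0.2, score_threshold = 2L) {
  stopifnot(is.data.frame(nodal))
  needed <- c("di", "bi", "ci", "li")
  if (!all(needed %in% names(nodal))) {
    abort("`nodal` must contain columns di, bi, ci, li.")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("`top_fraction` must lie in (0, 1).")
  }
  n <- nrow(nodal)
  k <- ceiling(top_fraction * n)
  high_di <- seq_len(n) %in% top_k_nodes(nodal$di, k, decreasing = TRUE)
  high_bi <- seq_len(n) %in% top_k_nodes(nodal$bi, k, decreasing = TRUE)
  low_ci  <- seq_len(n) %in% top_k_nodes(nodal$ci, k, decreasing = FALSE)
  low_li  <- seq_len(n) %in% top_k_nodes(nodal$li, k, decreasing = FALSE)
  score <- as.integer(high_di) + as.integer(high_bi) +
    as.integer(low_ci) + as.integer(low_li)
  dplyr::mutate(tibble::as_tibble(nodal),
                high_di = high_di, high_bi = high_bi,
                low_ci = low_ci, low_li = low_li,
                score = score, is_hub = score >= score_threshold)
}

#' Subject-averaged nodal metrics
#'
#' Element-wise mean of each nodal metric across subjects, the group-level
#' table on which hub criteria are evaluated. Undefined nodal path lengths
#' are excluded from that node's mean, with the number of contributing
#' subjects reported.
#'
#' @param nodal_list List of per-subject [nodal_metrics()] tibbles with a
#'   common node set.
#' @return One tibble of averaged metrics with an `n_li_defined` column.
#' @export
group_nodal_means <- function(nodal_list) {
  if (length(nodal_list) == 0) abort("`nodal_list` must be non-empty.")
  n_nodes <- nrow(nodal_list[[1]])
  if (!all(vapply(nodal_list, nrow, integer(1)) == n_nodes)) {
    abort("All subjects must share the same node count.")
  }
  long <- dplyr::bind_rows(nodal_list, .id = ".subject")
  dplyr::summarise(
    dplyr::group_by(long, .data$node, .data$label),
    di = mean(.data$di), ei = mean(.data$ei), bi = mean(.data$bi),
    ci = mean(.data$ci),
    li = if (all(is.na(.data$li))) NA_real_ else mean(.data$li, na.rm = TRUE),
    n_li_defined = sum(!is.na(.data$li)),
    .groups = "drop")
}

#' Compare hub sets between two groups
#'
#' @param table1,table2 Hub tables from [hubness_scores()] over the same node
#'   set (conventionally group 1 = HC, group 2 = patients).
#' @return Object of class `wmnet_hub_comparison`: list with `shared`,
#'   `specific_group1`, `specific_group2` (vectors of node labels, pairwise
#'   disjoint).
#' @export
compare_hubs <- function(table1, table2) {
  if (!identical(table1$label, table2$label)) {
    abort("Hub tables must cover the same node set in the same order.")
  }
  h1 <- table1$label[table1$is_hub]
  h2 <- table2$label[table2$is_hub]
  structure(list(
    shared = intersect(h1, h2),
    specific_group1 = setdiff(h1, h2),
    specific_group2 = setdiff(h2, h1)
  ), class = "wmnet_hub_comparison")
}

#' @export
print.wmnet_hub_comparison <- function(x, ...) {
  cat("<wmnet_hub_comparison>\n")
  cat("  shared:          ", paste(x$shared, collapse = ", "), "\n")
  cat("  group-1 specific:", paste(x$specific_group1, collapse = ", "), "\n")
  cat("  group-2 specific:", paste(x$specific_group2, collapse = ", "), "\n")
  invisible(x)
}
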