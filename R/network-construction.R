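#' AAL-90 region labels
#'
#' Returns the 90-region anatomical parcellation used to label network nodes:
#' 45 bilateral regions in the standard single-subject ordering (odd indices
#' left, even indices right), each tagged with a coarse functional class
#' (primary, association, paralimbic, limbic, subcortical).
#'
#' @return A tibble with columns `index` (1-based node index), `abbrev`
#'   (region abbreviation, e.g. `"PreCG.L"`) and `class`.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "wmnet",
                      mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' Look up AAL-90 node indices by region abbreviation
#'
#' @param abbrevs Character vector of region abbreviations (e.g. `"PUT.L"`).
#' @return Integer vector of 1-based node indices.
#' @export
aal90_index <- function(abbrevs) {
  labels <- aal90_labels()
  idx <- match(abbrevs, labels$abbrev)
  if (anyNA(idx)) {
    abort(paste0("Unknown region abbreviation(s): ",
                 paste(abbrevs[is.na(idx)], collapse = ", ")))
  }
  labels$index[idx]
}

# --- validation -------------------------------------------------------------

validate_adjacency <- function(adj, arg = "adjacency") {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (any(is.na(adj)) || !all(adj %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 entries.", arg))
  }
  if (!isTRUE(all.equal(adj, t(adj), check.attributes = FALSE))) {
    abort(sprintf("`%s` must be symmetric.", arg))
  }
  if (any(diag(adj) != 0)) {
    abort(sprintf("`%s` must have a zero diagonal (no self-loops).", arg))
  }
  invisible(adj)
}

validate_counts <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    abort(sprintf("`%s` must contain non-negative integer counts.", arg))
  }
  bad <- which(counts != t(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "`%s` must be symmetric; first violation at row %d, column %d.",
      arg, bad[1, 1], bad[1, 2]))
  }
  if (any(diag(counts) != 0)) {
    abort(sprintf("`%s` must have a zero diagonal (no self-connections).", arg))
  }
  invisible(counts)
}

# --- construction -----------------------------------------------------------

#' Tally streamlines into a region-by-region count matrix
#'
#' Aggregates a per-streamline table (one row per reconstructed fiber joining
#' two regions) into a symmetric streamline-count connectivity matrix, the
#' substrate on which edge thresholds are applied.
#'
#' @param streamlines A data frame with columns `region_a` and `region_b`
#'   (1-based node indices); a `subject_id` column is carried into the result
#'   attribute if unique.
#' @param n_nodes Number of atlas nodes (default 90).
#' @return An `n_nodes` x `n_nodes` symmetric integer matrix of counts with a
#'   zero diagonal.
#' @export
count_streamlines <- function(streamlines, n_nodes = 90L) {
  stopifnot(is.data.frame(streamlines))
  a <- as.integer(streamlines$region_a)
  b <- as.integer(streamlines$region_b)
  if (length(a) != length(b)) abort("region_a and region_b lengths differ.")
  counts <- matrix(0L, n_nodes, n_nodes)
  if (length(a) > 0) {
    self <- which(a == b)
    if (length(self) > 0) {
      abort(sprintf("Self-pair streamline at row %d (region %d).",
                    self[1], a[self[1]]))
    }
    if (any(a < 1 | a > n_nodes | b < 1 | b > n_nodes)) {
      abort(sprintf("Region index out of range 1..%d.", n_nodes))
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    # tally each unordered pair once into the strict lower triangle, then mirror
    counts <- matrix(tabulate(hi + (lo - 1L) * n_nodes, nbins = n_nodes^2),
                     n_nodes, n_nodes)
    counts <- counts + t(counts)
    storage.mode(counts) <- "integer"
  }
  counts
}

#' Threshold a count matrix into a binary network
#'
#' An edge is drawn between two regions when at least `fn` streamlines connect
#' them (fiber-number threshold); the default of 3 is the primary threshold,
#' with 1--5 swept for robustness.
#'
#' @param counts Symmetric non-negative integer count matrix (zero diagonal).
#' @param fn Integer fiber-number threshold, >= 1.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
#' @examples
#' counts <- matrix(0L, 4, 4); counts[1, 2] <- counts[2, 1] <- 3L
#' threshold_network(counts, fn = 3)[1, 2]
threshold_network <- function(counts, fn = 3L) {
  validate_counts(counts)
  fn <- as.integer(fn)
  if (length(fn) != 1 || is.na(fn) || fn < 1) {
    abort("`fn` must be a single integer >= 1.")
  }
  adj <- (counts >= fn) * 1L
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  adj
}

#' Apply a sweep of fiber-number thresholds
#'
#' @param counts Count matrix as in [threshold_network()].
#' @param fn_values Integer thresholds to apply (default 1:5).
#' @return Named list of adjacency matrices, one per threshold; names are
#'   `"fn1"`, `"fn2"`, ... Edge sets are nested (non-increasing in `fn`).
#' @export
sweep_thresholds <- function(counts, fn_values = 1:5) {
  if (length(fn_values) == 0) abort("`fn_values` must be non-empty.")
  nets <- lapply(fn_values, function(fn) threshold_network(counts, fn))
  names(nets) <- paste0("fn", fn_values)
  nets
}

# --- file I/O ---------------------------------------------------------------

#' Read a streamline-count matrix from a delimited text file
#'
#' Accepts whitespace- or comma-delimited square numeric matrices and
#' validates the connectivity-matrix invariants (symmetry, integer
#' non-negative entries, zero diagonal), failing with a message naming the
#' first violation.
#'
#' @param path Path to the matrix file.
#' @return Validated integer count matrix.
#' @export
load_count_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Matrix in %s is not square (%d x %d).",
                  path, nrow(m), ncol(m)))
  }
  validate_counts(m, arg = basename(path))
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as tab-delimited text
#'
#' @param counts Count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  validate_counts(counts)
  write.table(counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
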