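# broom-style accessors for the analysis object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an analysis into the group-comparison table
#'
#' @param x A `wmnet_analysis` object.
#' @param which One of `"global"` (default), `"nodal"`, `"correlations"`,
#'   `"demographics"`, `"hubs"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wmnet_analysis
#' @export
tidy.wmnet_analysis <- function(x, which = c("global", "nodal",
                                             "correlations", "demographics",
                                             "hubs"), ...) {
  which <- match.arg(which)
  if (which == "hubs") {
    return(dplyr::bind_rows(x$hubs$tables, .id = "group"))
  }
  tibble::as_tibble(x$stats[[which]])
}

#' One-row summary of an analysis
#'
#' @param x A `wmnet_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: group sizes, group-mean small-worldness at the
#'   primary threshold, counts of significant global parameters and
#'   Bonferroni-surviving nodal tests, hub counts.
#' @method glance wmnet_analysis
#' @export
glance.wmnet_analysis <- function(x, ...) {
  lv <- levels(factor(x$cohort$group))
  sig_primary <- vapply(lv, function(gr) {
    mean(x$global$sigma[x$cohort$group == gr])
  }, numeric(1))
  tibble::tibble(
    n_group1 = sum(x$cohort$group == lv[1]),
    n_group2 = sum(x$cohort$group == lv[2]),
    primary_fn = x$params$primary_fn,
    sigma_group1 = sig_primary[1],
    sigma_group2 = sig_primary[2],
    n_significant_global = sum(x$stats$global$significant),
    n_significant_nodal = sum(x$stats$nodal$significant),
    n_hubs_group1 = sum(x$hubs$tables[[1]]$is_hub),
    n_hubs_group2 = sum(x$hubs$tables[[2]]$is_hub))
}
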