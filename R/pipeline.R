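# End-to-end orchestration: cohort -> networks -> metrics -> nulls -> hubs
# -> group statistics.

#' Analyze a cohort of streamline-count matrices
#'
#' Runs the full analysis: thresholds every subject's count matrix at each
#' fiber-number threshold, computes global parameters (with degree-preserving
#' null normalization) across the sweep, computes nodal metrics and hub
#' tables at the primary threshold, and produces the group statistical
#' report.
#'
#' @param counts Named list of per-subject count matrices (names = subject
#'   ids).
#' @param cohort Cohort tibble with `subject_id`, `group`, covariates and
#'   clinical columns; row order must match `counts`.
#' @param fn_thresholds Integer sweep of fiber-number thresholds.
#' @param primary_fn Threshold used for nodal metrics, hubs and group tables.
#' @param m Null-ensemble size per network (0 skips normalization).
#' @param swap_factor Rewiring intensity of the null ensembles.
#' @param top_fraction,score_threshold Hub criteria (see [hubness_scores()]).
#' @param alpha Significance level for flagging.
#' @param seed Integer seed driving the null ensembles.
#' @return Object of class `wmnet_analysis`: list with
#'   * `sweep` — per-subject global metrics at every threshold,
#'   * `global` — per-subject global metrics at `primary_fn`,
#'   * `nodal` — named list of per-subject nodal tables at `primary_fn`,
#'   * `hubs` — per-group hub tables and their comparison,
#'   * `stats` — the `wmnet_group_analysis` report,
#'   * `params` — run parameters.
#' @export
analyze_cohort <- function(counts, cohort,
                           fn_thresholds = 1:5, primary_fn = 3L,
                           m = 100L, swap_factor = 10,
                           top_fraction = 0.2, score_threshold = 2L,
                           alpha = 0.05, seed = 1L) {
  stopifnot(is.list(counts), is.data.frame(cohort))
  if (!identical(names(counts), cohort$subject_id)) {
    abort("`names(counts)` must match `cohort$subject_id` in order.")
  }
  if (!primary_fn %in% fn_thresholds) {
    abort("`primary_fn` must be one of `fn_thresholds`.")
  }
  n_sub <- length(counts)

  sweep_rows <- vector("list", n_sub * length(fn_thresholds))
  nodal <- vector("list", n_sub)
  global_rows <- vector("list", n_sub)
  r <- 0L
  for (i in seq_len(n_sub)) {
    nets <- sweep_thresholds(counts[[i]], fn_thresholds)
    for (k in seq_along(fn_thresholds)) {
      fn <- fn_thresholds[k]
      adj <- nets[[k]]
      ens <- if (m > 0 && sum(adj) / 2 >= 2) {
        build_ensemble(adj, m = m, swap_factor = swap_factor,
                       seed = as.integer(seed) + 1000L * i + fn)
      } else NULL
      gm <- global_metrics(adj, ens)
      gm <- dplyr::mutate(gm, subject_id = cohort$subject_id[i], fn = fn,
                          .before = 1)
      r <- r + 1L
      sweep_rows[[r]] <- gm
      if (fn == primary_fn) {
        global_rows[[i]] <- gm
        nodal[[i]] <- nodal_metrics(adj)
      }
    }
  }
  sweep <- dplyr::bind_rows(sweep_rows)
  global_tbl <- dplyr::bind_rows(global_rows)
  names(nodal) <- cohort$subject_id

  lv <- levels(factor(cohort$group))
  hub_tables <- lapply(lv, function(gr) {
    means <- group_nodal_means(nodal[cohort$group == gr])
    hubness_scores(means, top_fraction = top_fraction,
                   score_threshold = score_threshold)
  })
  names(hub_tables) <- lv
  hubs <- list(tables = hub_tables,
               comparison = compare_hubs(hub_tables[[1]], hub_tables[[2]]))

  stats <- run_group_analysis(global_tbl, nodal, cohort, alpha = alpha)

  structure(list(sweep = sweep, global = global_tbl, nodal = nodal,
                 hubs = hubs, stats = stats, cohort = cohort,
                 params = list(fn_thresholds = fn_thresholds,
                               primary_fn = primary_fn, m = m,
                               swap_factor = swap_factor,
                               top_fraction = top_fraction,
                               score_threshold = score_threshold,
                               alpha = alpha, seed = seed)),
            class = "wmnet_analysis")
}

#' @export
print.wmnet_analysis <- function(x, ...) {
  cat(sprintf("<wmnet_analysis> %d subjects, FN sweep {%s}, primary FN = %d, m = %d nulls\n",
              nrow(x$cohort), paste(x$params$fn_thresholds, collapse = ","),
              x$params$primary_fn, x$params$m))
  print(x$stats)
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"` (read
#'   count matrices and metadata from disk).
#' @param cohort A [cohort_config()] for simulate mode.
#' @param manifest For load mode: path to a TSV with columns `subject_id`,
#'   `path` binding matrix files to metadata rows.
#' @param metadata For load mode: path to the cohort CSV (columns
#'   `subject_id`, `group`, `age`, `gender`, `education`, `pta`, `thi`,
#'   `duration`).
#' @param out_dir Output directory for report tables.
#' @param seed Integer seed.
#' @inheritParams analyze_cohort
#' @return A list of class `wmnet_run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       cohort = cohort_config(),
                       manifest = NULL, metadata = NULL,
                       fn_thresholds = 1:5, primary_fn = 3L,
                       m = 100L, swap_factor = 10,
                       top_fraction = 0.2, score_threshold = 2L,
                       alpha = 0.05, out_dir = "wmnet_run", seed = 1L) {
  mode <- match.arg(mode)
  if (!primary_fn %in% fn_thresholds) {
    abort("`primary_fn` must be one of `fn_thresholds`.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (mode == "load" && (is.null(manifest) || is.null(metadata))) {
    abort("Load mode needs both `manifest` and `metadata` paths.")
  }
  structure(as.list(environment()), class = "wmnet_run_config")
}

read_cohort_inputs <- function(config) {
  meta <- tibble::as_tibble(read.table(config$metadata, header = TRUE,
                                       sep = ",", stringsAsFactors = FALSE))
  man <- read.table(config$manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(man))) {
    abort("Manifest must have columns subject_id and path.")
  }
  idx <- match(meta$subject_id, man$subject_id)
  if (anyNA(idx)) {
    abort(paste0("Manifest is missing subject(s): ",
                 paste(meta$subject_id[is.na(idx)], collapse = ", ")))
  }
  counts <- lapply(man$path[idx], load_count_matrix)
  names(counts) <- meta$subject_id
  meta$group <- factor(meta$group)
  list(counts = counts, cohort = meta)
}

#' Run the full pipeline and write report tables
#'
#' Executes simulate/analyze/report end to end: obtains the cohort (from the
#' generator or from disk), runs [analyze_cohort()], and writes
#' tab-separated report tables (threshold sweep, global and nodal group
#' comparisons, hub tables, correlations, demographics) plus a JSON run
#' summary into `config$out_dir`.
#'
#' @param config A [run_config()] object.
#' @return The `wmnet_analysis` object, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wmnet_run_config"))
  inputs <- if (config$mode == "simulate") {
    coh <- generate_cohort(config$cohort)
    list(counts = coh$counts, cohort = coh$cohort)
  } else {
    read_cohort_inputs(config)
  }
  an <- analyze_cohort(inputs$counts, inputs$cohort,
                       fn_thresholds = config$fn_thresholds,
                       primary_fn = config$primary_fn,
                       m = config$m, swap_factor = config$swap_factor,
                       top_fraction = config$top_fraction,
                       score_threshold = config$score_threshold,
                       alpha = config$alpha, seed = config$seed)
  write_report(an, config$out_dir)
  invisible(an)
}

write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the report tables of an analysis
#'
#' @param analysis A `wmnet_analysis` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "wmnet_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- analysis$stats
  write_tsv_table(analysis$sweep, file.path(out_dir, "sweep_global_metrics.tsv"))
  write_tsv_table(st$demographics, file.path(out_dir, "demographics.tsv"))
  write_tsv_table(st$global, file.path(out_dir, "global_comparison.tsv"))
  write_tsv_table(st$nodal, file.path(out_dir, "nodal_comparison.tsv"))
  write_tsv_table(st$correlations, file.path(out_dir, "correlations.tsv"))
  for (gr in names(analysis$hubs$tables)) {
    write_tsv_table(analysis$hubs$tables[[gr]],
                    file.path(out_dir, paste0("hub_table_", gr, ".tsv")))
  }
  cmp <- analysis$hubs$comparison
  hub_cmp <- tibble::tibble(
    label = c(cmp$shared, cmp$specific_group1, cmp$specific_group2),
    classification = rep(c("shared",
                           paste0("specific_", names(analysis$hubs$tables)[1]),
                           paste0("specific_", names(analysis$hubs$tables)[2])),
                         c(length(cmp$shared), length(cmp$specific_group1),
                           length(cmp$specific_group2))))
  write_tsv_table(hub_cmp, file.path(out_dir, "hub_comparison.tsv"))

  group_sigma <- dplyr::summarise(
    dplyr::group_by(
      dplyr::left_join(analysis$sweep,
                       analysis$cohort[, c("subject_id", "group")],
                       by = "subject_id"),
      .data$group, .data$fn),
    sigma = mean(.data$sigma), .groups = "drop")
  summary <- list(
    package_version = as.character(utils::packageVersion("wmnet")),
    seed = analysis$params$seed,
    params = analysis$params[c("fn_thresholds", "primary_fn", "m",
                               "swap_factor", "top_fraction",
                               "score_threshold", "alpha")],
    n_subjects = nrow(analysis$cohort),
    n_per_group = as.list(table(analysis$cohort$group)),
    group_mean_sigma = group_sigma,
    significant_global = st$global$metric[st$global$significant],
    n_significant_nodal = sum(st$nodal$significant),
    n_hubs = lapply(analysis$hubs$tables, function(t) sum(t$is_hub)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
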