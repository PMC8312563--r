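# Group-level statistics: demographics tests, covariate-adjusted GLM
# comparisons, Bonferroni correction, and confound-adjusted Pearson
# correlations.

#' Pooled-variance two-sample t-test
#'
#' Two-tailed independent-samples t-test with pooled variance
#' (`df = n1 + n2 - 2`). When both groups are constant and equal, `t = 0`
#' and `p = 1` by convention.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble: `t`, `p`, `df`, `mean_x`, `sd_x`, `mean_y`,
#'   `sd_y`.
#' @export
ttest_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("Each group needs n >= 2.")
  df <- length(x) + length(y) - 2
  if (sd(x) == 0 && sd(y) == 0) {
    tt <- list(statistic = if (mean(x) == mean(y)) 0 else Inf,
               p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    tt <- t.test(x, y, var.equal = TRUE)
  }
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value, df = df,
                 mean_x = mean(x), sd_x = sd(x),
                 mean_y = mean(y), sd_y = sd(y))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1; errors on a zero row or column
#' marginal.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return One-row tibble: `chi2`, `p`, `df`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) || sum(counts) == 0) {
    abort("`counts` must be a non-negative 2x2 table with a positive total.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Chi-square test undefined: a row or column marginal is zero.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Covariate-adjusted group comparison of one metric
#'
#' Ordinary least squares of the metric on an intercept, a group indicator,
#' and the age, gender, and education covariates. The reported `t` is for
#' the group term, signed so that a positive value means the adjusted
#' control (first-level) mean exceeds the patient mean; `df = n - 5`.
#'
#' @param cohort Cohort tibble with columns `group` (2-level factor, first
#'   level = controls), `age`, `gender`, `education`.
#' @param values Numeric vector of the metric, aligned with `cohort` rows.
#' @param metric_name Label carried into the result.
#' @return One-row tibble of class row: `metric`, `estimate` (adjusted
#'   control-minus-patient difference), `t`, `p`, `df`, per-group raw
#'   `mean`/`sd`.
#' @export
glm_group_test <- function(cohort, values, metric_name = "metric") {
  stopifnot(is.data.frame(cohort), length(values) == nrow(cohort))
  g <- cohort$group
  if (!is.factor(g)) g <- factor(g)
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  dat <- data.frame(
    y = values,
    hc = as.numeric(g == levels(g)[1]),
    age = cohort$age,
    gender = as.numeric(factor(cohort$gender)) - 1,
    education = cohort$education)
  if (any(!complete.cases(dat))) abort("Missing values in metric or covariates.")
  fit <- lm(y ~ hc + age + gender + education, data = dat)
  if (anyNA(coef(fit))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  # constant or exactly-fit metrics trigger summary.lm's perfect-fit warning;
  # such rows are legitimate here (e.g. an always-absent node's degree)
  sm <- suppressWarnings(summary(fit))$coefficients["hc", ]
  g1 <- values[g == levels(g)[1]]; g2 <- values[g == levels(g)[2]]
  tibble::tibble(
    metric = metric_name,
    estimate = unname(sm["Estimate"]),
    t = unname(sm["t value"]),
    p = unname(sm["Pr(>|t|)"]),
    df = fit$df.residual,
    mean_group1 = mean(g1), sd_group1 = sd(g1),
    mean_group2 = mean(g2), sd_group2 = sd(g2))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * n_tests)` with a fixed family size (default: the 90
#' atlas nodes), so a partial list of node-level p-values is still corrected
#' against the full family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param n_tests Family size, >= `length(p)`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, n_tests = 90L) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  if (n_tests < length(p)) abort("`n_tests` must be >= length(p).")
  p.adjust(p, method = "bonferroni", n = n_tests)
}

#' Confound-adjusted Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals; the two-sided p-value uses
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - n_covariates`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix or data frame of confounders (or `NULL`
#'   for a plain Pearson correlation).
#' @return One-row tibble: `r`, `p`, `df`, `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    keep <- keep & complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - 2L - k
  if (df < 1) abort("Too few complete observations for the requested model.")
  if (k > 0) {
    qx <- qr(cbind(1, covariates))
    if (qx$rank < k + 1) abort("Covariate design is rank deficient.")
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero-variance residuals; correlation undefined.")
    return(tibble::tibble(r = NA_real_, p = NA_real_, df = df, n = n))
  }
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt(df / (1 - r^2))
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df)
  tibble::tibble(r = r, p = p, df = df, n = n)
}

#' Full group-level statistical report
#'
#' Assembles the study's statistical tables from per-subject metrics:
#' demographics (t-tests for age/education/PTA, chi-square for gender),
#' covariate-adjusted global-parameter comparisons (uncorrected p), nodal
#' comparisons of degree/efficiency/betweenness with Bonferroni correction
#' over the node family applied separately per centrality type, and
#' confound-adjusted correlations of the global parameters with the
#' patients' clinical variables (PTA, THI, duration).
#'
#' @param global_tbl Per-subject global metrics: tibble with `subject_id`
#'   plus metric columns (`cp`, `lp`, `loce`, `ge`, and optionally `gamma`,
#'   `lambda`, `sigma`).
#' @param nodal_list Named list (by subject id) of [nodal_metrics()] tibbles.
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param alpha Significance level used for flagging (default 0.05).
#' @return Object of class `wmnet_group_analysis`: list of tibbles
#'   `demographics`, `global`, `nodal`, `correlations`.
#' @export
run_group_analysis <- function(global_tbl, nodal_list, cohort, alpha = 0.05) {
  stopifnot(is.data.frame(global_tbl), is.data.frame(cohort))
  stopifnot(identical(global_tbl$subject_id, cohort$subject_id))
  g <- cohort$group
  lv <- levels(factor(g))
  hc <- g == lv[1]

  demographics <- dplyr::bind_rows(
    dplyr::mutate(ttest_two_sample(cohort$age[hc], cohort$age[!hc]),
                  variable = "age", test = "t"),
    dplyr::mutate(ttest_two_sample(cohort$education[hc], cohort$education[!hc]),
                  variable = "education", test = "t"),
    dplyr::mutate(ttest_two_sample(cohort$pta[hc], cohort$pta[!hc]),
                  variable = "pta", test = "t"),
    {
      tab <- table(cohort$gender, g)
      if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
          all(colSums(tab) > 0)) {
        dplyr::mutate(chi_square_2x2(tab), variable = "gender", test = "chi2")
      } else {
        tibble::tibble(variable = "gender", test = "chi2",
                       chi2 = NA_real_, p = NA_real_)
      }
    })
  demographics <- dplyr::relocate(demographics, "variable", "test")

  metric_cols <- intersect(c("gamma", "lambda", "sigma", "cp", "lp",
                             "loce", "ge"), names(global_tbl))
  metric_cols <- metric_cols[vapply(metric_cols, function(mc) {
    all(!is.na(global_tbl[[mc]]))
  }, logical(1))]
  global <- purrr::map_dfr(metric_cols, function(mc) {
    glm_group_test(cohort, global_tbl[[mc]], metric_name = mc)
  })
  global$significant <- global$p < alpha

  nodal_long <- dplyr::bind_rows(nodal_list, .id = "subject_id")
  n_nodes <- nrow(nodal_list[[1]])
  nodal <- purrr::map_dfr(c("di", "ei", "bi"), function(mc) {
    wide <- tidyr::pivot_wider(
      nodal_long[, c("subject_id", "node", mc)],
      names_from = "node", values_from = dplyr::all_of(mc))
    stopifnot(identical(wide$subject_id, cohort$subject_id))
    res <- purrr::map_dfr(seq_len(n_nodes), function(nd) {
      out <- glm_group_test(cohort, wide[[as.character(nd)]],
                            metric_name = mc)
      out$node <- nd
      out
    })
    res$p_bonferroni <- bonferroni(res$p, n_tests = n_nodes)
    res
  })
  labels <- nodal_list[[1]]$label
  nodal$label <- labels[nodal$node]
  nodal$significant <- nodal$p_bonferroni < alpha
  nodal <- dplyr::relocate(nodal, "metric", "node", "label")

  # correlations within the patient group, confounds regressed out
  pt <- !hc
  covs <- cbind(age = cohort$age[pt],
                gender = as.numeric(factor(cohort$gender))[pt] - 1,
                education = cohort$education[pt])
  clin_vars <- c("pta", "thi", "duration")
  correlations <- purrr::map_dfr(metric_cols, function(mc) {
    purrr::map_dfr(clin_vars, function(cv) {
      y <- cohort[[cv]][pt]
      n_ok <- sum(!is.na(y) & complete.cases(covs))
      if (n_ok < 2 + ncol(covs) + 2) return(NULL)
      res <- partial_pearson(global_tbl[[mc]][pt], y, covs)
      dplyr::mutate(res, parameter = mc, clinical = cv, .before = 1)
    })
  })

  structure(list(demographics = demographics, global = global,
                 nodal = nodal, correlations = correlations,
                 alpha = alpha, group_levels = lv),
            class = "wmnet_group_analysis")
}

#' @export
print.wmnet_group_analysis <- function(x, ...) {
  cat("<wmnet_group_analysis>\n")
  cat(sprintf("  groups: %s vs %s (alpha = %g)\n",
              x$group_levels[1], x$group_levels[2], x$alpha))
  cat(sprintf("  global parameters significant: %s\n",
              paste(x$global$metric[x$global$significant], collapse = ", ")))
  cat(sprintf("  nodal tests passing Bonferroni: %d of %d\n",
              sum(x$nodal$significant), nrow(x$nodal)))
  invisible(x)
}
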