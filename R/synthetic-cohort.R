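# Synthetic two-group cohort generator.
#
# Emulates the structure of a case-control connectome study: a shared
# small-world substrate (rewired ring lattice), per-subject topological
# noise, a patient-specific shift toward randomization plus targeted nodal
# degree deficits, Poisson streamline counts on top of the binary truth, and
# covariates/clinical scores with a rank-coupled association between disease
# burden and network integration.

#' Cohort generator configuration
#'
#' Collects and validates every knob of the synthetic cohort. Defaults
#' emulate the study conditions the pipeline is designed for: 91 controls vs
#' 145 patients on a 90-node parcellation, a rewired-lattice small-world
#' substrate (mean degree 6, rewiring 0.1), patients shifted toward
#' randomization (extra rewiring 0.3) combined with severe edge deficits at
#' eight affected regions (bilateral inferior frontal operculum, right
#' triangular inferior frontal gyrus, right medial superior frontal gyrus,
#' right superior occipital gyrus, bilateral putamen, right superior
#' temporal pole) so that the patients' networks lose both segregation
#' (lower clustering, local efficiency) and integration (longer paths,
#' lower global efficiency); hub regions (PreCG, PCUN, CAU, PUT
#' bilaterally) are planted in the shared substrate, and covariates and
#' clinical scores follow the cohort's demographic structure.
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_nodes Number of atlas nodes (>= 4).
#' @param base_mean_degree Even lattice degree (< `n_nodes`).
#' @param base_rewire_prob Watts-Strogatz rewiring probability of the shared
#'   substrate.
#' @param patient_extra_rewire Additional edge-rewiring fraction applied to
#'   patient networks (the randomization shift).
#' @param subject_edge_noise Per-pair edge flip probability modeling
#'   tractography variability.
#' @param planted_hub_nodes Integer node indices boosted to hub status in the
#'   shared substrate.
#' @param hub_boost Extra edges attached to each planted hub.
#' @param planted_deficit_nodes Named numeric vector: names are node indices,
#'   values the fraction of incident edges removed in patients.
#' @param count_mean_present,count_mean_absent Poisson means of streamline
#'   counts on true edges / non-edges.
#' @param age_mean,age_sd Age distribution (years), truncated to \[18, 80\].
#' @param prop_male Bernoulli probability of male gender.
#' @param education_mean,education_sd Education (years), truncated to
#'   \[5, 25\].
#' @param pta_hc_mean,pta_hc_sd,pta_pt_mean,pta_pt_sd Pure-tone average
#'   (dB HL) distributions for controls and patients.
#' @param thi_mean,thi_sd Tinnitus Handicap Inventory (patients), truncated
#'   to \[0, 100\].
#' @param duration_mean,duration_sd Hearing-loss duration in days (patients),
#'   truncated to \[1, 14\].
#' @param cor_thi,cor_duration Target rank-coupled correlations between each
#'   patient's realized path-length surrogate and THI / duration.
#' @param seed Integer master seed.
#' @return A validated list of class `wmnet_cohort_config`.
#' @export
cohort_config <- function(n_controls = 91L,
                          n_patients = 145L,
                          n_nodes = 90L,
                          base_mean_degree = 6L,
                          base_rewire_prob = 0.1,
                          patient_extra_rewire = 0.3,
                          subject_edge_noise = 0.01,
                          planted_hub_nodes = c(1L, 2L, 67L, 68L, 71L, 72L, 73L, 74L),
                          hub_boost = 8L,
                          planted_deficit_nodes = setNames(
                            rep(0.8, 8), c(11, 12, 14, 24, 50, 73, 74, 84)),
                          count_mean_present = 20,
                          count_mean_absent = 0.3,
                          age_mean = 38.5, age_sd = 12,
                          prop_male = 0.5,
                          education_mean = 13, education_sd = 3.5,
                          pta_hc_mean = 12.08, pta_hc_sd = 4.04,
                          pta_pt_mean = 78.17, pta_pt_sd = 28.56,
                          thi_mean = 45.57, thi_sd = 24.88,
                          duration_mean = 8.44, duration_sd = 4.17,
                          cor_thi = 0.18, cor_duration = -0.18,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_nodes < 4) abort("`n_nodes` must be >= 4.")
  if (cfg$base_mean_degree %% 2 != 0) abort("`base_mean_degree` must be even.")
  if (cfg$base_mean_degree < 2 || cfg$base_mean_degree >= cfg$n_nodes) {
    abort("`base_mean_degree` must be in [2, n_nodes).")
  }
  probs <- c(cfg$base_rewire_prob, cfg$patient_extra_rewire,
             cfg$subject_edge_noise, cfg$prop_male)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (cfg$count_mean_present <= cfg$count_mean_absent) {
    abort("`count_mean_present` must exceed `count_mean_absent`.")
  }
  if (cfg$count_mean_absent < 0) abort("`count_mean_absent` must be >= 0.")
  if (length(cfg$planted_hub_nodes) > 0 &&
      any(cfg$planted_hub_nodes < 1 | cfg$planted_hub_nodes > cfg$n_nodes)) {
    abort("`planted_hub_nodes` out of node range.")
  }
  if (length(cfg$planted_deficit_nodes) > 0) {
    idx <- as.integer(names(cfg$planted_deficit_nodes))
    if (anyNA(idx) || any(idx < 1 | idx > cfg$n_nodes)) {
      abort("`planted_deficit_nodes` names must be node indices in range.")
    }
    if (any(cfg$planted_deficit_nodes < 0 | cfg$planted_deficit_nodes > 1)) {
      abort("Deficit fractions must lie in [0, 1].")
    }
  }
  if (abs(cfg$cor_thi) > 1 || abs(cfg$cor_duration) > 1) {
    abort("Target correlations must lie in [-1, 1].")
  }
  structure(cfg, class = "wmnet_cohort_config")
}

#' @export
print.wmnet_cohort_config <- function(x, ...) {
  cat(sprintf(
    "<wmnet_cohort_config> %d controls vs %d patients, %d nodes (k = %d, p = %.2f; patient extra rewire %.2f), seed %d\n",
    x$n_controls, x$n_patients, x$n_nodes, x$base_mean_degree,
    x$base_rewire_prob, x$patient_extra_rewire, x$seed))
  invisible(x)
}

#' Small-world base topology
#'
#' Builds a Watts-Strogatz-style substrate: a ring lattice in which every
#' node connects to its `mean_degree` nearest neighbors, then each lattice
#' edge is independently rewired with probability `rewire_prob` by
#' re-attaching one endpoint to a uniformly chosen node that creates neither
#' a self-loop nor a duplicate edge. Edge count is conserved.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param mean_degree Even lattice degree.
#' @param rewire_prob Rewiring probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Binary adjacency matrix.
#' @export
#' @examples
#' adj <- generate_base_topology(90, 6, 0.1, seed = 1)
#' sum(adj) / 2  # 270 edges, conserved under rewiring
generate_base_topology <- function(n_nodes, mean_degree, rewire_prob,
                                   seed = NULL) {
  if (n_nodes < 4) abort("`n_nodes` must be >= 4.")
  if (mean_degree %% 2 != 0) abort("`mean_degree` must be even.")
  if (mean_degree < 2 || mean_degree >= n_nodes) {
    abort("`mean_degree` must be in [2, n_nodes).")
  }
  if (rewire_prob < 0 || rewire_prob > 1) abort("`rewire_prob` not in [0, 1].")
  if (!is.null(seed)) set.seed(as.integer(seed))
  adj <- matrix(0L, n_nodes, n_nodes)
  half <- mean_degree %/% 2
  for (offset in seq_len(half)) {
    i <- seq_len(n_nodes)
    j <- ((i - 1 + offset) %% n_nodes) + 1
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  if (rewire_prob > 0) {
    edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      if (runif(1) < rewire_prob) {
        u <- edges[e, 1]; v <- edges[e, 2]
        candidates <- which(adj[u, ] == 0L)
        candidates <- setdiff(candidates, u)
        if (length(candidates) > 0) {
          w <- candidates[sample.int(length(candidates), 1)]
          adj[u, v] <- adj[v, u] <- 0L
          adj[u, w] <- adj[w, u] <- 1L
        }
      }
    }
  }
  adj
}

# Remove a fraction of the edges incident to each named deficit node
# (uniformly chosen, rounded down).
apply_deficits <- function(adj, deficit_spec) {
  for (k in seq_along(deficit_spec)) {
    node <- as.integer(names(deficit_spec)[k])
    if (is.na(node) || node < 1 || node > nrow(adj)) {
      abort(sprintf("Deficit node index out of range: %s",
                    names(deficit_spec)[k]))
    }
    nb <- which(adj[node, ] == 1L)
    n_remove <- floor(deficit_spec[[k]] * length(nb))
    if (n_remove > 0) {
      drop <- nb[sample.int(length(nb), n_remove)]
      adj[node, drop] <- 0L
      adj[drop, node] <- 0L
    }
  }
  adj
}

#' Derive a per-subject network from the base topology
#'
#' Applies, in order: (1) Watts-Strogatz-style rewiring of a fraction
#' `extra_rewire` of edges (the patient randomization shift); (2) removal of
#' the specified fraction of edges incident to each deficit node (rounded
#' down, uniformly chosen); (3) independent edge flips at rate `edge_noise`
#' over all node pairs (per-subject tractography noise).
#'
#' @param base Binary adjacency matrix (the shared substrate).
#' @param extra_rewire Fraction of edges to rewire, \[0, 1\].
#' @param edge_noise Per-pair flip probability, \[0, 1\].
#' @param deficit_spec Named numeric vector (node index -> fraction removed)
#'   or `NULL`.
#' @param seed Optional integer seed.
#' @return Binary adjacency matrix, simple and undirected.
#' @export
generate_subject_network <- function(base, extra_rewire = 0, edge_noise = 0,
                                     deficit_spec = NULL, seed = NULL) {
  validate_adjacency(base, arg = "base")
  if (!is.null(seed)) set.seed(as.integer(seed))
  adj <- base
  storage.mode(adj) <- "integer"
  if (extra_rewire > 0) {
    edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      if (adj[u, v] == 1L && runif(1) < extra_rewire) {
        candidates <- setdiff(which(adj[u, ] == 0L), u)
        if (length(candidates) > 0) {
          w <- candidates[sample.int(length(candidates), 1)]
          adj[u, v] <- adj[v, u] <- 0L
          adj[u, w] <- adj[w, u] <- 1L
        }
      }
    }
  }
  if (length(deficit_spec) > 0) adj <- apply_deficits(adj, deficit_spec)
  if (edge_noise > 0) {
    ut <- which(upper.tri(adj))
    flip <- ut[runif(length(ut)) < edge_noise]
    adj[flip] <- 1L - adj[flip]
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  }
  diag(adj) <- 0L
  adj
}

#' Sample streamline counts on top of a binary network
#'
#' For each unordered node pair, draws a Poisson count with mean
#' `mean_present` when the edge exists in the truth network and
#' `mean_absent` otherwise; the diagonal is zero.
#'
#' @param net Binary adjacency matrix (the true edge set).
#' @param mean_present,mean_absent Poisson means, with
#'   `mean_present > mean_absent` and `mean_absent >= 0`.
#' @param seed Optional integer seed.
#' @return Symmetric integer count matrix.
#' @export
sample_counts <- function(net, mean_present = 20, mean_absent = 0.3,
                          seed = NULL) {
  validate_adjacency(net, arg = "net")
  if (mean_present <= mean_absent || mean_absent < 0) {
    abort("Require mean_present > mean_absent >= 0.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(net)
  counts <- matrix(0L, n, n)
  ut <- which(upper.tri(net))
  mu <- ifelse(net[ut] == 1L, mean_present, mean_absent)
  counts[ut] <- rpois(length(ut), mu)
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  counts
}

# Truncated-normal draws by resampling out-of-range values.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Reorder `values` so its rank correlation with `anchor` approximates
# `target_r`: build a latent score mixing the anchor's normal scores with
# independent noise, then match sorted values to the score's ranks.
rank_couple <- function(values, anchor, target_r) {
  n <- length(values)
  if (n < 2 || target_r == 0) return(values)
  zs <- scale(rank(anchor, ties.method = "average"))[, 1]
  latent <- target_r * zs + sqrt(1 - target_r^2) * rnorm(n)
  sort(values)[rank(latent, ties.method = "first")]
}

#' Generate a full synthetic cohort
#'
#' Simulates the two-group study: a shared small-world substrate with planted
#' hub regions, per-subject control/patient networks, Poisson streamline
#' counts, covariates, and clinical variables with THI and duration
#' rank-coupled to each patient's realized characteristic path length (the
#' network-integration surrogate). Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `wmnet_cohort`: list with
#'   * `counts` — named list of per-subject streamline-count matrices,
#'   * `cohort` — tibble of subject metadata (`subject_id`, `group`, `age`,
#'     `gender`, `education`, `pta`, `thi`, `duration`, plus the generator
#'     diagnostic `lp_surrogate`),
#'   * `base_network` — the shared substrate adjacency,
#'   * `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_controls = 4, n_patients = 4, seed = 7)
#' coh <- generate_cohort(cfg)
#' coh$cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "wmnet_cohort_config"))
  cfg <- config
  base <- generate_base_topology(cfg$n_nodes, cfg$base_mean_degree,
                                 cfg$base_rewire_prob, seed = cfg$seed)
  # plant hubs: attach extra edges so the designated regions dominate the
  # degree ranking in both groups
  set.seed(cfg$seed + 500000L)
  for (h in cfg$planted_hub_nodes) {
    candidates <- setdiff(which(base[h, ] == 0L), h)
    n_add <- min(cfg$hub_boost, length(candidates))
    if (n_add > 0) {
      add <- candidates[sample.int(length(candidates), n_add)]
      base[h, add] <- 1L
      base[add, h] <- 1L
    }
  }

  n_total <- cfg$n_controls + cfg$n_patients
  group <- rep(c("HC", "SSNHL"), c(cfg$n_controls, cfg$n_patients))
  subject_id <- sprintf("%s%03d", ifelse(group == "HC", "hc", "pt"),
                        c(seq_len(cfg$n_controls), seq_len(cfg$n_patients)))

  counts <- vector("list", n_total)
  lp_surrogate <- numeric(n_total)
  for (i in seq_len(n_total)) {
    net <- if (group[i] == "HC") {
      generate_subject_network(base, extra_rewire = 0,
                               edge_noise = cfg$subject_edge_noise,
                               seed = cfg$seed + i)
    } else {
      generate_subject_network(base, extra_rewire = cfg$patient_extra_rewire,
                               edge_noise = cfg$subject_edge_noise,
                               deficit_spec = cfg$planted_deficit_nodes,
                               seed = cfg$seed + i)
    }
    lp_surrogate[i] <-
      characteristic_path_length(bfs_distances(net))$lp
    counts[[i]] <- sample_counts(net, cfg$count_mean_present,
                                 cfg$count_mean_absent,
                                 seed = cfg$seed + 100000L + i)
  }
  names(counts) <- subject_id

  set.seed(cfg$seed + 900000L)
  age <- rnorm_trunc(n_total, cfg$age_mean, cfg$age_sd, 18, 80)
  gender <- ifelse(rbinom(n_total, 1, cfg$prop_male) == 1, "male", "female")
  education <- rnorm_trunc(n_total, cfg$education_mean, cfg$education_sd, 5, 25)
  is_pt <- group == "SSNHL"
  pta <- numeric(n_total)
  pta[!is_pt] <- rnorm_trunc(sum(!is_pt), cfg$pta_hc_mean, cfg$pta_hc_sd, 0, 25)
  pta[is_pt] <- rnorm_trunc(sum(is_pt), cfg$pta_pt_mean, cfg$pta_pt_sd, 30, 120)
  thi <- rep(NA_real_, n_total)
  duration <- rep(NA_real_, n_total)
  thi_raw <- rnorm_trunc(sum(is_pt), cfg$thi_mean, cfg$thi_sd, 0, 100)
  dur_raw <- rnorm_trunc(sum(is_pt), cfg$duration_mean, cfg$duration_sd, 1, 14)
  thi[is_pt] <- rank_couple(thi_raw, lp_surrogate[is_pt], cfg$cor_thi)
  duration[is_pt] <- rank_couple(dur_raw, lp_surrogate[is_pt],
                                 cfg$cor_duration)

  cohort <- tibble::tibble(
    subject_id = subject_id,
    group = factor(group, levels = c("HC", "SSNHL")),
    age = age, gender = gender, education = education,
    pta = pta, thi = thi, duration = duration,
    lp_surrogate = lp_surrogate
  )
  structure(list(counts = counts, cohort = cohort,
                 base_network = base, config = cfg),
            class = "wmnet_cohort")
}

#' @export
print.wmnet_cohort <- function(x, ...) {
  cat(sprintf("<wmnet_cohort> %d subjects (%d HC, %d SSNHL), %d nodes\n",
              nrow(x$cohort), sum(x$cohort$group == "HC"),
              sum(x$cohort$group == "SSNHL"), x$config$n_nodes))
  invisible(x)
}

#' Expand a count matrix back into a streamline table
#'
#' Emits one row per streamline for every unordered region pair; the round
#' trip through [count_streamlines()] reproduces the input exactly.
#'
#' @param counts Symmetric count matrix.
#' @param subject_id Subject identifier carried in the table.
#' @return A tibble with columns `subject_id`, `region_a`, `region_b`
#'   (`region_a < region_b`).
#' @export
expand_to_streamlines <- function(counts, subject_id = "subject") {
  validate_counts(counts)
  ut <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    return(tibble::tibble(subject_id = character(), region_a = integer(),
                          region_b = integer()))
  }
  reps <- counts[upper.tri(counts)][counts[upper.tri(counts)] > 0]
  # ut rows are in the same (column-major upper-triangle) order as reps
  tibble::tibble(
    subject_id = subject_id,
    region_a = rep(ut[, 1], reps),
    region_b = rep(ut[, 2], reps)
  )
}
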