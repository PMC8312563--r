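test_that("zero rewiring yields the pure ring lattice", {
  expect_equal(generate_base_topology(6, 2, 0), cycle_graph(6),
               ignore_attr = TRUE)
  lat <- generate_base_topology(90, 6, 0)
  expect_equal(degree_centrality(lat), rep(6L, 90))
})

test_that("rewiring conserves the edge count and rejects bad arguments", {
  for (seed in 1:10) {
    adj <- generate_base_topology(90, 6, 0.1, seed = seed)
    expect_equal(sum(adj) / 2, 270)
    validate_ok <- function(a) {
      isTRUE(all.equal(a, t(a))) && all(diag(a) == 0) && all(a %in% 0:1)
    }
    expect_true(validate_ok(adj))
  }
  expect_error(generate_base_topology(90, 5, 0.1), "even")
  expect_error(generate_base_topology(3, 2, 0.1), ">= 4")
})

test_that("subject networks: identity, deficit degrees, clustering loss", {
  base <- generate_base_topology(30, 4, 0.1, seed = 1)
  expect_equal(generate_subject_network(base, 0, 0, NULL, seed = 1), base,
               ignore_attr = TRUE)

  # a 50% deficit on a degree-6 node halves its degree (before noise)
  lat <- generate_base_topology(20, 6, 0)
  out <- generate_subject_network(lat, 0, 0, c(`7` = 0.5), seed = 2)
  expect_equal(sum(out[7, ]), 3)
  expect_error(generate_subject_network(lat, 0, 0, c(`99` = 0.5)),
               "out of range")

  # extra rewiring destroys triangles on average
  lat6 <- generate_base_topology(40, 6, 0)
  cp0 <- clustering_coef(lat6)$cp
  cps <- sapply(1:50, function(s) {
    clustering_coef(generate_subject_network(lat6, 0.3, 0, NULL, seed = s))$cp
  })
  expect_lt(mean(cps), cp0)
})

test_that("Poisson counts respect edge structure and recover edges at FN=3", {
  net <- generate_base_topology(30, 4, 0.2, seed = 3)
  c0 <- sample_counts(net, 10, 0, seed = 1)
  expect_true(all(c0[net == 0L] == 0))          # mean 0 off the edge set
  expect_true(all(diag(c0) == 0))
  empty <- matrix(0L, 6, 6)
  expect_true(all(diag(sample_counts(empty, 5, 0.5, seed = 1)) == 0))

  # FN = 3 re-thresholding is a high-fidelity edge detector for the default
  # count model (Poisson tails: P(Pois(20) < 3) ~ 1e-6, P(Pois(0.3) >= 3) ~ 3.6e-3)
  tp <- fp <- numeric(100)
  for (s in 1:100) {
    counts <- sample_counts(net, 20, 0.3, seed = s)
    rec <- threshold_network(counts, 3)
    tp[s] <- sum(rec[net == 1L] == 1L) / sum(net == 1L)
    fp[s] <- sum(rec[net == 0L] == 1L) / sum(net == 0L)
  }
  expect_gte(mean(tp), 0.99)
  expect_lte(mean(fp), 0.01)
})

test_that("cohort generation is deterministic with the documented shape", {
  cfg <- cohort_config(n_controls = 5, n_patients = 7, seed = 11)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$counts, coh2$counts)
  expect_identical(coh1$cohort, coh2$cohort)
  expect_equal(nrow(coh1$cohort), 12)
  expect_equal(as.integer(table(coh1$cohort$group)), c(5, 7))
  expect_true(all(coh1$cohort$thi[coh1$cohort$group == "SSNHL"] >= 0))
  expect_true(all(coh1$cohort$thi[coh1$cohort$group == "SSNHL"] <= 100))
  expect_true(all(is.na(coh1$cohort$thi[coh1$cohort$group == "HC"])))
  expect_true(all(coh1$cohort$pta >= 0))
  expect_true(all(coh1$cohort$age >= 18 & coh1$cohort$age <= 80))

  different <- generate_cohort(cohort_config(n_controls = 5, n_patients = 7,
                                             seed = 12))
  expect_false(identical(coh1$counts, different$counts))
})

test_that("clinical coupling attains the target correlation at scale", {
  # strong target: sample r over patients should land near it
  rs <- sapply(1:10, function(s) {
    cfg <- cohort_config(n_controls = 4, n_patients = 145, cor_thi = 0.6,
                         seed = s)
    coh <- generate_cohort(cfg)
    pt <- coh$cohort$group == "SSNHL"
    cor(coh$cohort$thi[pt], coh$cohort$lp_surrogate[pt])
  })
  expect_true(all(rs > 0.4 & rs < 0.8))
  expect_gt(mean(rs), 0.45)
})

test_that("planted group effects are recoverable from the generated cohorts", {
  # patient Cp below control Cp and patient Lp above control Lp, per seed
  ok_cp <- ok_lp <- ok_di <- logical(10)
  for (s in 1:10) {
    coh <- generate_cohort(cohort_config(n_controls = 20, n_patients = 20,
                                         seed = 100 + s))
    met <- sapply(coh$counts, function(cm) {
      adj <- threshold_network(cm, 3)
      c(cp = clustering_coef(adj)$cp,
        lp = characteristic_path_length(shortest_paths(adj))$lp)
    })
    hc <- coh$cohort$group == "HC"
    ok_cp[s] <- mean(met["cp", !hc]) < mean(met["cp", hc])
    ok_lp[s] <- mean(met["lp", !hc]) > mean(met["lp", hc])
    deficit_nodes <- as.integer(names(coh$config$planted_deficit_nodes))
    di <- sapply(coh$counts, function(cm) {
      rowSums(threshold_network(cm, 3))[deficit_nodes]
    })
    ok_di[s] <- mean(di[, !hc]) < mean(di[, hc])
  }
  expect_true(all(ok_cp))
  expect_true(all(ok_lp))
  expect_true(all(ok_di))
})
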