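test_that("simulated phenotype tables classify back to the configured arm sizes", {
  sim <- simulate_cohorts(small_config())
  for (co in sim$cohorts) {
    lab <- classify_samples(co$phenotypes, co$patterns)
    cfg_row <- small_config()$cohorts
    cfg_row <- cfg_row[cfg_row$name == co$name, ]
    expect_identical(sum(lab == "TN"), cfg_row$n_tn)
    expect_identical(sum(lab == "ERPOS"), cfg_row$n_er)
    expect_identical(sum(lab == "EXCLUDED"), 0L)
  }
})

test_that("the generator is deterministic under a fixed seed and plants the stated shift", {
  s1 <- simulate_cohorts(small_config())
  s2 <- simulate_cohorts(small_config())
  expect_identical(s1$cohorts$cA$expression, s2$cohorts$cA$expression)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(
    s1$cohorts$cA$expression,
    simulate_cohorts(small_config(seed = 43))$cohorts$cA$expression))

  # empirical TN-ER mean difference of shifted genes ~ delta * sd
  cfg <- simulation_config(
    cohorts = data.frame(name = "big", n_tn = 150L, n_er = 150L,
                         dialect = "standard", stringsAsFactors = FALSE),
    n_genes = 300L, n_motif_sets = 6L, n_planted_sets = 2L,
    cohort_participation = 1, probes_per_gene = 1,
    withdrawn_fraction = 0, seed = 9)
  sim <- simulate_cohorts(cfg)
  co <- build_cohort("big", sim$cohorts$big$expression,
                     sim$cohorts$big$probe_map, sim$cohorts$big$phenotypes,
                     sim$cohorts$big$patterns)
  sh <- unlist(sim$truth$shifted_genes, use.names = FALSE)
  d <- rowMeans(co$values[sh, co$labels == "TN"]) -
    rowMeans(co$values[sh, co$labels == "ERPOS"])
  expect_equal(mean(d), 1.0, tolerance = 0.1)
  null_genes <- setdiff(rownames(co$values), sh)[1:50]
  d0 <- rowMeans(co$values[null_genes, co$labels == "TN"]) -
    rowMeans(co$values[null_genes, co$labels == "ERPOS"])
  expect_lt(abs(mean(d0)), 0.1)
})

test_that("withdrawn probes and multi-probe genes survive the round trip through preprocess", {
  sim <- simulate_cohorts(small_config())
  co <- sim$cohorts$cA
  expect_gt(sum(co$probe_map$withdrawn), 0L)
  expect_gt(nrow(co$expression), 300L)  # probe expansion
  built <- build_cohort(co$name, co$expression, co$probe_map,
                        co$phenotypes, co$patterns)
  expect_identical(nrow(built$values), 300L)
  expect_false("WITHDRAWN" %in% rownames(built$values))
})

test_that("perturbation sets carry the configured containment of shifted genes", {
  sim <- simulate_cohorts(small_config())
  pert <- simulate_perturbation_collection(sim$truth, containment = 0.6,
                                           low_containment = 0.2, seed = 10)
  for (i in seq_len(nrow(pert$key))) {
    k <- pert$key[i, ]
    if (is.na(k$planted_set)) next
    sh <- sim$truth$shifted_genes[[k$planted_set]]
    got <- length(intersect(pert$collection$sets[[k$set_name]], sh))
    if (k$direction == "DN")
      expect_identical(got, as.integer(floor(k$containment * length(sh))))
  }
  # with the shifted genes as signature, 0.6-containment DN sets pass at
  # 50% and 0.2-containment decoys fail
  for (s in sim$truth$planted_sets) {
    m <- match_signature(sim$truth$shifted_genes[[s]], pert$collection,
                         signature_name = s)
    hi <- pert$key$set_name[which(pert$key$planted_set == s &
                                    pert$key$containment == 0.6)]
    lo <- pert$key$set_name[which(pert$key$planted_set == s &
                                    pert$key$containment == 0.2)]
    expect_true(m$passes[m$set_name == hi])
    expect_false(m$passes[m$set_name == lo])
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_planted_sets = 99, n_motif_sets = 10))
  expect_error(simulation_config(penetrance = 0))
})
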