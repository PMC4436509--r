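test_that("signal-to-noise applies the sd floor and is antisymmetric in labels", {
  co <- structure(list(values = rbind(G1 = c(2, 2, 1, 1)),
                       labels = c("TN", "TN", "ERPOS", "ERPOS")),
                  class = "expression_cohort")
  colnames(co$values) <- paste0("s", 1:4)
  # zero variance in both arms: floor 0.2*|mu| engages, (2-1)/(0.4+0.2)
  expect_equal(unname(signal_to_noise(co)), 1 / 0.6, tolerance = 1e-12)

  set.seed(21)
  co2 <- make_cohort(50, 8, 8)
  m <- signal_to_noise(co2)
  expect_true(all(is.finite(m)))
  swapped <- co2
  swapped$labels <- ifelse(co2$labels == "TN", "ERPOS", "TN")
  expect_equal(signal_to_noise(swapped), -m, tolerance = 1e-12)
  # identical distributions in both arms score exactly zero
  co3 <- co2
  co3$values <- cbind(co2$values[, 1:8], co2$values[, 1:8])
  colnames(co3$values) <- paste0("s", 1:16)
  co3$labels <- rep(c("TN", "ERPOS"), each = 8)
  expect_equal(max(abs(signal_to_noise(co3))), 0)
  co4 <- co2
  co4$labels[co4$labels == "TN"] <- c("TN", rep("ERPOSX", 7))
  expect_error(signal_to_noise(co4), ">= 2 samples")
})

test_that("enrichment score matches hand-computed walks at the extremes", {
  r <- rank_genes(stats::setNames(c(3, 2, 1, -4), c("A", "B", "C", "D")))
  top <- enrichment_score(r, "A")
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, "A")
  bottom <- enrichment_score(r, "D", weight_exponent = 0)
  expect_equal(bottom$es, -1)
  expect_identical(bottom$leading_edge, "D")
  expect_equal(bottom$running_sum, c(-1 / 3, -2 / 3, -1, 0),
               tolerance = 1e-12)
  expect_error(enrichment_score(r, "ZZZ"), "no overlap")
  expect_error(enrichment_score(r, c("A", "B", "C", "D")), "no misses")
})

test_that("enrichment score equals the brute-force walk and stays in [-1, 1]", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    ranked <- rank_genes(stats::setNames(rnorm(n), sprintf("g%03d", 1:n)))
    k <- sample(seq_len(n - 1), 1)
    genes <- sample(names(ranked), k)
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(ranked, genes, weight_exponent = w)
    expect_equal(es$es, oracle_es(ranked, genes, w), tolerance = 1e-12)
    expect_true(abs(es$es) <= 1)
    expect_lt(abs(es$running_sum[n]), 1e-9)  # walk returns to zero
    # internal positional form agrees with the full walk
    fast <- motifsig:::.es_from_positions(
      es$hit_positions, abs(ranked[es$hit_positions])^w, n)
    expect_equal(fast, es$es, tolerance = 1e-12)
    # positive rescaling of the metric leaves the weighted ES unchanged
    if (w == 1) {
      es2 <- enrichment_score(ranked * 3.7, genes, weight_exponent = 1)
      expect_equal(es2$es, es$es, tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    ranked <- rank_genes(stats::setNames(rnorm(n), sprintf("g%03d", 1:n)))
    genes <- sample(names(ranked), sample(3:10, 1))
    mine <- enrichment_score(ranked, genes, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(unname(ranked),
                               which(names(ranked) %in% genes),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values hit the floor for planted sets and have the right support", {
  set.seed(51)
  planted <- sprintf("G%04d", 1:12)
  co <- make_cohort(n_genes = 300, n_tn = 25, n_er = 30,
                    shift_genes = planted, delta = 2)
  res <- permutation_null(co, planted, n_perm = 99, seed = 7)
  expect_equal(res$p_nominal, 1 / (res$n_perm_same_sign + 1))
  expect_gt(res$es, 0)
  expect_true(all(res$leading_edge %in% planted))
  expect_gte(res$p_nominal, 1 / 100)
  one <- permutation_null(co, planted, n_perm = 1, seed = 8)
  expect_true(one$p_nominal %in% c(1 / 2, 1))
})

test_that("run_gsea filters undersized sets, is deterministic, and ranks planted sets first", {
  set.seed(61)
  planted <- sprintf("G%04d", 1:16)
  co <- make_cohort(n_genes = 300, n_tn = 20, n_er = 25,
                    shift_genes = planted, delta = 1.5)
  coll <- gene_set_collection(list(
    PLANTED = planted,
    NULLSET = sprintf("G%04d", 101:118),
    TINY = sprintf("G%04d", 200:209)), kind = "motif")
  expect_message(res <- run_gsea(co, coll, min_size = 15, n_perm = 100,
                                 seed = 3), "filtered")
  expect_identical(sort(res$set_name), c("NULLSET", "PLANTED"))
  expect_identical(res$set_name[1], "PLANTED")
  expect_identical(res$direction[res$set_name == "PLANTED"], "TN_enriched")
  expect_true(all(res$p_nominal >= 1 / (res$n_perm + 1)))
  res2 <- suppressMessages(run_gsea(co, coll, min_size = 15, n_perm = 100,
                                    seed = 3))
  expect_identical(res, res2)
  expect_identical(nrow(suppressMessages(
    run_gsea(co, gene_set_collection(list(), "motif"), n_perm = 10))), 0L)
})
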