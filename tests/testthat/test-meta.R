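test_that("Stouffer weighted Z satisfies its closed forms and invariances", {
  # all p = 0.5 combine to 0.5 regardless of weights
  expect_equal(stouffer_weighted_z(rep(0.5, 4), c(1, 9, 2, 5))$p, 0.5,
               tolerance = 1e-12)
  # single study: weights cancel
  expect_equal(stouffer_weighted_z(0.01, weights = 3)$p, 0.01,
               tolerance = 1e-12)
  # k = 2, equal weights: p = 1 - pnorm(2 qnorm(0.95) / sqrt(2))
  expect_equal(stouffer_weighted_z(c(0.05, 0.05))$p,
               1 - pnorm(2 * qnorm(0.95) / sqrt(2)), tolerance = 1e-10)
  # weight scale invariance
  p <- c(0.02, 0.3, 0.11)
  w <- c(2, 5, 1)
  expect_equal(stouffer_weighted_z(p, w)$z,
               stouffer_weighted_z(p, 100 * w)$z, tolerance = 1e-12)
  # monotonicity: decreasing any single p never increases the combined p
  set.seed(71)
  for (i in 1:50) {
    k <- sample(2:7, 1)
    p <- runif(k, 0.001, 0.999)
    w <- runif(k, 0.5, 5)
    base <- stouffer_weighted_z(p, w)$p
    j <- sample(k, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    expect_lte(stouffer_weighted_z(p2, w)$p, base)
  }
  expect_error(stouffer_weighted_z(c(0.5, 0), c(1, 1)), "inside \\(0, 1\\)")
  expect_error(stouffer_weighted_z(0.5, weights = -1), "positive")
  # clipping rescues boundary values (rounded display zeros)
  expect_lt(stouffer_weighted_z(c(0, 0.02), clip = c(0.0005, 0.9995))$p, 0.01)
})

test_that("cohort combination is order-invariant and renormalizes missing cohorts", {
  mk <- function(sets, p, dir = "TN_enriched") {
    df <- data.frame(set_name = sets, size = 20L, es = 0.5, nes = 1.2,
                     p_nominal = p, n_perm = 1000L, n_perm_same_sign = 500L,
                     direction = dir, stringsAsFactors = FALSE)
    df$leading_edge <- replicate(length(sets), c("A", "B"), simplify = FALSE)
    df
  }
  res <- list(c1 = mk(c("S1", "S2"), c(0.01, 0.2)),
              c2 = mk(c("S1", "S3"), c(0.03, 0.4)),
              c3 = mk("S1", 0.02))
  sizes <- c(c1 = 100, c2 = 400, c3 = 225)
  meta <- combine_cohorts(res, sizes)
  expect_identical(meta$set_name[1], "S1")
  expect_identical(meta$n_cohorts[meta$set_name == "S1"], 3L)
  # single-cohort set keeps that cohort's p
  expect_equal(meta$p_combined[meta$set_name == "S2"], 0.2, tolerance = 1e-12)
  # permuting cohort order changes nothing
  meta2 <- combine_cohorts(res[c(3, 1, 2)], sizes)
  expect_equal(meta, meta2)
  # manual check of the sqrt(n)-weighted combination for S1
  st <- stouffer_weighted_z(c(0.01, 0.03, 0.02), sqrt(c(100, 400, 225)))
  expect_equal(meta$z_combined[meta$set_name == "S1"], st$z,
               tolerance = 1e-12)
  # ER-enriched rows never reach the meta stage
  res$c1$direction <- c("ER_enriched", "TN_enriched")
  expect_identical(
    combine_cohorts(res, sizes)$n_cohorts[meta$set_name == "S1"], 2L)
})

test_that("the significance gate is strict at alpha", {
  meta <- data.frame(set_name = c("A", "B", "C"),
                     p_combined = c(0.0099, 0.0101, 0.5),
                     rank = 1:3, stringsAsFactors = FALSE)
  expect_identical(gate_and_rank(meta, 0.01)$set_name, "A")
  expect_identical(nrow(gate_and_rank(meta[0, ], 0.01)), 0L)
})

test_that("consensus signatures keep the genes at maximum cohort support", {
  cs <- consensus_signature("S", list(c1 = c("A", "B"), c2 = c("B", "C")))
  expect_identical(cs$genes, "B")
  expect_identical(cs$max_support, 2L)
  expect_identical(cs$support_counts, c(A = 1L, B = 2L, C = 1L))
  single <- consensus_signature("S", list(c1 = c("Z", "Q")))
  expect_identical(single$genes, c("Q", "Z"))
  expect_identical(single$max_support, 1L)
  expect_error(consensus_signature("S", list(c1 = character())), "empty")
  # ten genes in 6 of 7 cohorts, none in all 7 -> a 10-gene signature at 6
  genes10 <- sprintf("T%02d", 1:10)
  edges <- lapply(1:7, function(i) genes10)
  for (i in 1:10) edges[[1 + (i %% 7)]] <-
    setdiff(edges[[1 + (i %% 7)]], genes10[i])
  names(edges) <- paste0("c", 1:7)
  cs7 <- consensus_signature("GCNF_LIKE", edges)
  expect_identical(cs7$max_support, 6L)
  expect_identical(length(cs7$genes), 10L)
})

test_that("build_signatures uses TN-enriched leading edges only", {
  df1 <- data.frame(set_name = "S", size = 5L, es = 0.4, nes = 1, p_nominal = 0.1,
                    n_perm = 10L, n_perm_same_sign = 5L,
                    direction = "TN_enriched", stringsAsFactors = FALSE)
  df1$leading_edge <- list(c("A", "B"))
  df2 <- df1
  df2$direction <- "ER_enriched"
  df2$es <- -0.4
  df2$leading_edge <- list(c("C"))
  sigs <- build_signatures(list(c1 = df1, c2 = df2), "S")
  expect_identical(sigs$S$genes, c("A", "B"))
  expect_identical(sigs$S$max_support, 1L)
})
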