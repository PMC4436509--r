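toy_map <- function(probes, symbols) {
  data.frame(probe_id = probes, accession = paste0("A_", probes),
             symbol = symbols, withdrawn = symbols == "WITHDRAWN",
             stringsAsFactors = FALSE)
}

test_that("probe collapse takes the per-sample maximum and drops withdrawn probes", {
  vals <- rbind(p1 = c(5, 1), p2 = c(2, 4), p3 = c(9, 9), p4 = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  map <- toy_map(c("p1", "p2", "p3", "p4"),
                 c("GENEA", "GENEA", "WITHDRAWN", "GENEB"))
  out <- collapse_probes(vals, map)
  expect_identical(rownames(out), c("GENEA", "GENEB"))
  expect_equal(unname(out["GENEA", ]), c(5, 4))  # max per sample, not per probe
  expect_equal(unname(out["GENEB", ]), c(1, 1))  # single probe is identity
  expect_false("WITHDRAWN" %in% rownames(out))
  # collapsing an already-collapsed matrix is the identity
  map2 <- toy_map(rownames(out), rownames(out))
  expect_equal(collapse_probes(out, map2), out)
  # alternative rule picks probe p1 (higher mean) everywhere
  out2 <- collapse_probes(vals, map, collapse = "global_max_mean")
  expect_equal(unname(out2["GENEA", ]), c(5, 1))
})

test_that("probe collapse rejects unmapped probes and all-withdrawn input", {
  vals <- rbind(p1 = c(1, 2))
  colnames(vals) <- c("s1", "s2")
  expect_error(collapse_probes(vals, toy_map("px", "G")), "missing from map")
  expect_error(collapse_probes(vals, toy_map("p1", "WITHDRAWN")),
               "no probes survive")
})

test_that("IHC codes classify by pattern with X wildcard, case-sensitively", {
  std <- phenotype_patterns("NNN", "PXN")
  mb <- phenotype_patterns("Nn1", "PX1")
  ph <- data.frame(sample_id = paste0("s", 1:6),
                   ihc_code = c("NNN", "PPN", "PNN", "nnn", NA, "NNP"),
                   stringsAsFactors = FALSE)
  lab <- classify_samples(ph, std)
  expect_identical(unname(lab),
                   c("TN", "ERPOS", "ERPOS", "EXCLUDED", "EXCLUDED",
                     "EXCLUDED"))
  ph2 <- data.frame(sample_id = c("m1", "m2", "m3"),
                    ihc_code = c("Nn1", "PP1", "NNN"),
                    stringsAsFactors = FALSE)
  expect_identical(unname(classify_samples(ph2, mb)),
                   c("TN", "ERPOS", "EXCLUDED"))
  expect_error(phenotype_patterns("NN", "PXN"), "3-character")
})

test_that("build_cohort drops excluded samples and records arm counts", {
  set.seed(5)
  vals <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  map <- toy_map(c("p1", "p2"), c("GA", "GB"))
  ph <- data.frame(sample_id = paste0("s", 1:6),
                   ihc_code = c("NNN", "NNN", "NNN", "PPN", "PNN", NA),
                   stringsAsFactors = FALSE)
  co <- build_cohort("toy", vals, map, ph, phenotype_patterns("NNN", "PXN"))
  expect_identical(ncol(co$values), 5L)
  expect_identical(co$n_tn, 3L)
  expect_identical(co$n_er, 2L)
  expect_identical(co$n_tn + co$n_er, sum(co$labels != "EXCLUDED"))
  ph$ihc_code <- rep(NA_character_, 6)
  expect_error(build_cohort("toy", vals, map, ph,
                            phenotype_patterns("NNN", "PXN")), "empty arm")
})

test_that("cohort summaries add a grand-total row", {
  set.seed(6)
  cos <- list(make_cohort(20, 4, 5, name = "a"),
              make_cohort(20, 3, 6, name = "b"))
  sm <- summarize_cohorts(cos)
  expect_identical(sm$n[sm$cohort == "TOTAL"], 18L)
  expect_identical(sm$n, sm$n_tn + sm$n_er)
  one <- summarize_cohorts(cos[1])
  expect_identical(one$n[one$cohort == "TOTAL"], one$n[1])
})
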