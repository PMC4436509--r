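# Brute-force oracle for the weighted KS enrichment score: a literal
# per-position walk, kept independent of the package implementation.
oracle_es <- function(ranked, genes, w = 1) {
  nm <- names(ranked)
  hit <- nm %in% genes
  n <- length(ranked)
  nh <- sum(hit)
  nr <- sum(abs(ranked[hit])^w)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) {
      if (nr > 0) cur + abs(ranked[i])^w / nr else cur + 1 / nh
    } else {
      cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  hi <- max(running); lo <- min(running)
  if (hi >= abs(lo)) hi else lo
}

# Small in-memory cohort: genes x (n_tn + n_er) Gaussian matrix with an
# optional mean shift on `shift_genes` in the TN arm.
make_cohort <- function(n_genes = 100, n_tn = 10, n_er = 12,
                        shift_genes = character(), delta = 0,
                        name = "toy", sd = 1, mean0 = 8) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  n <- n_tn + n_er
  vals <- matrix(rnorm(n_genes * n, mean0, sd), n_genes, n,
                 dimnames = list(genes, sprintf("%s_s%03d", name,
                                                seq_len(n))))
  if (length(shift_genes) > 0)
    vals[shift_genes, seq_len(n_tn)] <-
      vals[shift_genes, seq_len(n_tn), drop = FALSE] + delta * sd
  structure(list(name = name, values = vals,
                 labels = stats::setNames(rep(c("TN", "ERPOS"),
                                              c(n_tn, n_er)),
                                          colnames(vals)),
                 n_tn = n_tn, n_er = n_er, n_excluded = 0L),
            class = "expression_cohort")
}

random_collection <- function(n_sets = 5, universe = sprintf("G%03d", 1:60),
                              kind = "motif") {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(3:12, 1)))
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  gene_set_collection(sets, kind = kind,
                      descriptions = sprintf("random set %d",
                                             seq_len(n_sets)))
}

# Desk-scale simulation: three small cohorts, shared by several tests.
small_config <- function(seed = 42) {
  simulation_config(
    cohorts = data.frame(
      name = c("cA", "cB", "cM"),
      n_tn = c(15L, 12L, 10L), n_er = c(20L, 18L, 14L),
      dialect = c("standard", "standard", "metabric"),
      stringsAsFactors = FALSE),
    n_genes = 300L, n_motif_sets = 10L, set_size_range = c(15L, 18L),
    n_planted_sets = 2L, planted_set_size = 15L,
    effect_size = 1.0, penetrance = 0.6, cohort_participation = 6 / 7,
    seed = seed)
}

collections_identical <- function(a, b) {
  identical(a$sets, b$sets) && identical(a$descriptions, b$descriptions) &&
    identical(a$kind, b$kind)
}
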