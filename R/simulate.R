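#' Configuration for the synthetic multi-cohort study
#'
#' Describes a simulated study with the statistical structure the
#' enrichment workflow assumes: several cohorts with fixed TN / ER+ arm
#' sizes, Gaussian expression on a log-intensity-like scale, a motif
#' gene-set collection in which a few "planted" sets carry a real TN
#' shift, partial penetrance (only a fraction of a planted set's genes
#' are truly shifted, emulating leading edges), per-gene cohort
#' participation (each truly shifted gene is shifted in only a fraction
#' of the cohorts, emulating cross-cohort heterogeneity), multi-probe
#' genes with jitter, withdrawn probe identifiers, and two cohorts using
#' the METABRIC IHC-code dialect.
#'
#' The default arm sizes are the seven published breast-cancer cohorts
#' (TN/ER+: 49/65, 191/382, 114/165, 64/123, 69/344, 52/184, 58/228;
#' 2088 samples in total).
#'
#' @param cohorts data.frame with columns `name`, `n_tn`, `n_er`,
#'   `dialect` (`"standard"` or `"metabric"`).
#' @param n_genes number of genes in the universe.
#' @param n_motif_sets number of motif gene sets (drawn disjoint when
#'   the universe allows, so null sets give independent p-values).
#' @param set_size_range inclusive size range for non-planted sets.
#' @param n_planted_sets number of sets carrying a true TN shift.
#' @param planted_set_size size of each planted set.
#' @param effect_size standardized TN mean shift (in units of
#'   `noise_sd`) for truly shifted genes.
#' @param penetrance fraction of a planted set's genes truly shifted.
#' @param cohort_participation fraction of cohorts in which each truly
#'   shifted gene is shifted (rounded to an exact per-gene cohort
#'   count).
#' @param probes_per_gene probabilities for 1, 2, 3 probes per gene.
#' @param probe_jitter_sd sd of probe-level jitter around the gene
#'   value.
#' @param withdrawn_fraction fraction of extra probes carrying a
#'   withdrawn identifier.
#' @param noise_sd residual expression sd.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   means.
#' @param seed integer seed making the whole study reproducible.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(cohorts = NULL,
                              n_genes = 2000L,
                              n_motif_sets = 50L,
                              set_size_range = c(15L, 25L),
                              n_planted_sets = 4L,
                              planted_set_size = 20L,
                              effect_size = 1.0,
                              penetrance = 0.6,
                              cohort_participation = 6 / 7,
                              probes_per_gene = c(0.7, 0.2, 0.1),
                              probe_jitter_sd = 0.05,
                              withdrawn_fraction = 0.02,
                              noise_sd = 1.0,
                              baseline_mean = 8.0,
                              baseline_sd = 2.0,
                              seed = 1L) {
  if (is.null(cohorts))
    cohorts <- data.frame(
      name = c("FFPE_A", "FFPE_B", "AFFY_A", "AFFY_B",
               "ILMN_DISC", "ILMN_VAL", "RNASEQ"),
      n_tn = c(49L, 191L, 114L, 64L, 69L, 52L, 58L),
      n_er = c(65L, 382L, 165L, 123L, 344L, 184L, 228L),
      dialect = c("standard", "standard", "standard", "standard",
                  "metabric", "metabric", "standard"),
      stringsAsFactors = FALSE)
  stopifnot(all(c("name", "n_tn", "n_er", "dialect") %in% colnames(cohorts)),
            all(cohorts$n_tn > 0), all(cohorts$n_er > 0),
            n_genes > 0, n_motif_sets > 0,
            n_planted_sets <= n_motif_sets,
            penetrance > 0, penetrance <= 1,
            cohort_participation > 0, cohort_participation <= 1,
            effect_size >= 0, noise_sd > 0,
            length(probes_per_gene) >= 1, all(probes_per_gene >= 0))
  structure(list(cohorts = cohorts, n_genes = as.integer(n_genes),
                 n_motif_sets = as.integer(n_motif_sets),
                 set_size_range = as.integer(set_size_range),
                 n_planted_sets = as.integer(n_planted_sets),
                 planted_set_size = as.integer(planted_set_size),
                 effect_size = effect_size, penetrance = penetrance,
                 cohort_participation = cohort_participation,
                 probes_per_gene = probes_per_gene,
                 probe_jitter_sd = probe_jitter_sd,
                 withdrawn_fraction = withdrawn_fraction,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "simulation_config")
}

ihc_code_sets <- list(
  standard = list(tn = "NNN", er = c("PPN", "PNN"),
                  patterns = c("NNN", "PXN")),
  metabric = list(tn = "Nn1", er = c("PP1", "PN1"),
                  patterns = c("Nn1", "PX1")))

#' Simulate a multi-cohort expression study
#'
#' Generates, under a single seed: per-cohort probe-level expression
#' matrices, phenotype tables, probe maps (including withdrawn probes),
#' the motif gene-set collection with planted TN-enriched sets, and the
#' ground truth needed to validate recovery.  Truly shifted genes get a
#' `effect_size * noise_sd` mean increase in the TN arm of each cohort
#' the gene participates in; the per-gene participating cohorts are an
#' exact-count random subset (`round(cohort_participation * n_cohorts)`
#' cohorts per gene).
#'
#' @param config a [simulation_config].
#' @return List with elements
#'   * `cohorts`: named list per cohort of `name`, `expression`
#'     (probes x samples), `phenotypes`, `probe_map`, `patterns`;
#'   * `motif_sets`: [gene_set_collection] of kind `"motif"`;
#'   * `truth`: list with `planted_sets`, `shifted_genes` (per planted
#'     set), `gene_cohorts` (per shifted gene), `genes`, `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cf <- config
  genes <- sprintf("G%05d", seq_len(cf$n_genes))
  mu <- stats::setNames(stats::rnorm(cf$n_genes, cf$baseline_mean,
                                     cf$baseline_sd), genes)

  # motif sets: disjoint chunks of a shuffled gene pool while it lasts
  sizes <- c(rep(cf$planted_set_size, cf$n_planted_sets),
             sample(seq(cf$set_size_range[1], cf$set_size_range[2]),
                    cf$n_motif_sets - cf$n_planted_sets, replace = TRUE))
  pool <- sample(genes)
  sets <- vector("list", cf$n_motif_sets)
  offset <- 0L
  for (i in seq_len(cf$n_motif_sets)) {
    if (offset + sizes[i] <= length(pool)) {
      sets[[i]] <- pool[(offset + 1L):(offset + sizes[i])]
      offset <- offset + sizes[i]
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  names(sets) <- sprintf("MOTIF_%03d", seq_len(cf$n_motif_sets))
  planted <- names(sets)[seq_len(cf$n_planted_sets)]
  motif_sets <- gene_set_collection(sets, kind = "motif")

  n_cohorts <- nrow(cf$cohorts)
  k_part <- max(1L, round(cf$cohort_participation * n_cohorts))
  shifted <- lapply(planted, function(s) {
    g <- sets[[s]]
    sort(sample(g, round(cf$penetrance * length(g))))
  })
  names(shifted) <- planted
  gene_cohorts <- list()
  for (s in planted)
    for (g in shifted[[s]])
      gene_cohorts[[g]] <- sort(sample(cf$cohorts$name, k_part))
  all_shifted <- unlist(shifted, use.names = FALSE)

  cohorts <- vector("list", n_cohorts)
  names(cohorts) <- cf$cohorts$name
  for (ci in seq_len(n_cohorts)) {
    co <- cf$cohorts[ci, ]
    n <- co$n_tn + co$n_er
    samp <- sprintf("%s_S%04d", co$name, seq_len(n))
    tn_cols <- seq_len(co$n_tn)
    gvals <- matrix(stats::rnorm(cf$n_genes * n, 0, cf$noise_sd),
                    nrow = cf$n_genes, ncol = n,
                    dimnames = list(genes, samp)) + mu
    for (g in all_shifted)
      if (co$name %in% gene_cohorts[[g]])
        gvals[g, tn_cols] <- gvals[g, tn_cols] + cf$effect_size * cf$noise_sd

    # expand genes to probes with jitter, then inject withdrawn probes
    k <- sample(seq_along(cf$probes_per_gene), cf$n_genes, replace = TRUE,
                prob = cf$probes_per_gene)
    gene_of_probe <- rep(seq_len(cf$n_genes), k)
    n_probes <- length(gene_of_probe)
    pvals <- gvals[gene_of_probe, , drop = FALSE] +
      matrix(stats::rnorm(n_probes * n, 0, cf$probe_jitter_sd),
             nrow = n_probes)
    probe_ids <- sprintf("%s_PRB%06d", co$name, seq_len(n_probes))
    rownames(pvals) <- probe_ids
    symbol <- genes[gene_of_probe]
    n_wd <- round(cf$withdrawn_fraction * n_probes)
    if (n_wd > 0L) {
      wd_ids <- sprintf("%s_PRBWD%04d", co$name, seq_len(n_wd))
      wd_vals <- matrix(stats::rnorm(n_wd * n, cf$baseline_mean,
                                     cf$baseline_sd),
                        nrow = n_wd, dimnames = list(wd_ids, samp))
      pvals <- rbind(pvals, wd_vals)
      probe_ids <- c(probe_ids, wd_ids)
      symbol <- c(symbol, rep("WITHDRAWN", n_wd))
    }
    map <- data.frame(probe_id = probe_ids,
                      accession = sprintf("ACC%06d", seq_along(probe_ids)),
                      symbol = symbol,
                      withdrawn = symbol == "WITHDRAWN",
                      stringsAsFactors = FALSE)
    dial <- ihc_code_sets[[co$dialect]]
    codes <- c(rep(dial$tn, co$n_tn),
               sample(dial$er, co$n_er, replace = TRUE))
    cohorts[[ci]] <- list(
      name = co$name,
      expression = pvals,
      phenotypes = data.frame(sample_id = samp, ihc_code = codes,
                              stringsAsFactors = FALSE),
      probe_map = map,
      patterns = phenotype_patterns(dial$patterns[1], dial$patterns[2]))
  }

  list(cohorts = cohorts, motif_sets = motif_sets,
       truth = list(planted_sets = planted, shifted_genes = shifted,
                    gene_cohorts = gene_cohorts, genes = genes,
                    config = cf))
}

#' Simulate a perturbation gene-set collection with known containment
#'
#' Emulates a chemical/genetic-perturbation collection with paired
#' `_UP`/`_DN` sets.  For every planted motif set it creates one matched
#' `_DN` set containing a `containment` fraction of that set's truly
#' shifted genes (plus unrelated filler genes), one low-containment
#' `_DN` decoy at `low_containment`, a paired filler-only `_UP` set, and
#' `n_decoys` unrelated `_DN`/`_UP` decoy pairs.
#'
#' @param truth the `truth` element returned by [simulate_cohorts()].
#' @param containment fraction of truly shifted genes contained in each
#'   matched `_DN` set (default 0.6).
#' @param low_containment containment of the per-set decoy `_DN` sets
#'   (default 0.2).
#' @param n_decoys number of unrelated decoy pairs.
#' @param set_size total size of each perturbation set.
#' @param seed optional seed.
#' @return List with `collection` (a [gene_set_collection] of kind
#'   `"perturbation"`) and `key` (data.frame mapping each generated set
#'   to its planted set and containment; `NA` for unrelated decoys).
#' @export
simulate_perturbation_collection <- function(truth, containment = 0.6,
                                             low_containment = 0.2,
                                             n_decoys = 10L,
                                             set_size = 40L,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  planted_genes <- unique(unlist(truth$shifted_genes, use.names = FALSE))
  filler_pool <- setdiff(truth$genes, planted_genes)
  sets <- list()
  key <- list()
  add <- function(name, genes, planted_set, cont, direction) {
    sets[[name]] <<- genes
    key[[length(key) + 1L]] <<- data.frame(
      set_name = name, planted_set = planted_set, containment = cont,
      direction = direction, stringsAsFactors = FALSE)
  }
  for (i in seq_along(truth$planted_sets)) {
    s <- truth$planted_sets[i]
    sh <- truth$shifted_genes[[s]]
    take <- function(frac) sample(sh, max(0L, floor(frac * length(sh))))
    hi <- take(containment)
    lo <- take(low_containment)
    add(sprintf("CPD%02d_RESPONSE_DN", i),
        sample(c(hi, sample(filler_pool, set_size - length(hi)))),
        s, containment, "DN")
    add(sprintf("CPD%02d_RESPONSE_UP", i),
        sample(filler_pool, set_size), s, 0, "UP")
    add(sprintf("CPD%02dLOW_RESPONSE_DN", i),
        sample(c(lo, sample(filler_pool, set_size - length(lo)))),
        s, low_containment, "DN")
  }
  for (j in seq_len(n_decoys)) {
    add(sprintf("DECOY%02d_RESPONSE_DN", j), sample(filler_pool, set_size),
        NA_character_, NA_real_, "DN")
    add(sprintf("DECOY%02d_RESPONSE_UP", j), sample(filler_pool, set_size),
        NA_character_, NA_real_, "UP")
  }
  list(collection = gene_set_collection(sets, kind = "perturbation"),
       key = do.call(rbind, key))
}

#' Materialize a synthetic study on disk
#'
#' Writes, for each simulated cohort, the expression matrix, phenotype
#' table and probe map in the dialects the readers expect, plus the
#' motif and perturbation GMT files, a ground-truth table of truly
#' shifted genes, and a ready-to-run pipeline configuration
#' (`config.yaml`).
#'
#' @param config a [simulation_config].
#' @param dir output directory (created if needed).
#' @return The pipeline config path, invisibly.
#' @export
simulate_study <- function(config, dir) {
  sim <- simulate_cohorts(config)
  pert <- simulate_perturbation_collection(
    sim$truth, seed = if (!is.null(config$seed)) config$seed + 1L else NULL)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (co in sim$cohorts) {
    base <- file.path(dir, co$name)
    write_expression(co$expression, paste0(base, "_expression.tsv"))
    write_phenotypes(co$phenotypes, paste0(base, "_phenotypes.tsv"))
    write_probe_map(co$probe_map, paste0(base, "_probe_map.tsv"))
    entries[[co$name]] <- list(
      name = co$name,
      expression = paste0(co$name, "_expression.tsv"),
      phenotypes = paste0(co$name, "_phenotypes.tsv"),
      probe_map = paste0(co$name, "_probe_map.tsv"),
      tn_pattern = co$patterns$tn, er_pattern = co$patterns$er)
  }
  write_gmt(sim$motif_sets, file.path(dir, "motif_sets.gmt"))
  write_gmt(pert$collection, file.path(dir, "perturbation_sets.gmt"))
  truth_df <- data.frame(
    set_name = rep(names(sim$truth$shifted_genes),
                   lengths(sim$truth$shifted_genes)),
    gene = unlist(sim$truth$shifted_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  truth_df$cohorts <- vapply(truth_df$gene, function(g)
    paste(sim$truth$gene_cohorts[[g]], collapse = ","), "")
  utils::write.table(truth_df, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pert$key, file.path(dir, "perturbation_key.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(cohorts = unname(entries),
              motif_gmt = "motif_sets.gmt",
              perturbation_gmt = "perturbation_sets.gmt",
              gsea = list(min_size = 15L, max_size = 500L, n_perm = 200L,
                          weight_exponent = 1),
              alpha = 0.01, overlap_threshold = 0.5,
              weight = "sqrt_n",
              seed = if (is.null(config$seed)) 1L else config$seed,
              out_dir = "results")
  cfg_path <- file.path(dir, "config.yaml")
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("writing config.yaml requires the 'yaml' package")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
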