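#' Run the cross-cohort enrichment analysis in memory
#'
#' Executes the full workflow on already-built cohorts: per-cohort GSEA
#' against the motif collection, Stouffer weighted-Z combination across
#' cohorts, the `p < alpha` gate, consensus promoter-motif signatures,
#' and (when a perturbation collection is supplied) signature matching
#' and the down-regulator report.
#'
#' Per-cohort permutation streams are derived deterministically from the
#' top-level seed (`seed + cohort index`), so a rerun with the same
#' inputs and seed is identical.
#'
#' @param cohorts named list of `expression_cohort` objects.
#' @param motif_sets a [gene_set_collection] of kind `"motif"`.
#' @param perturbation_sets optional [gene_set_collection] of kind
#'   `"perturbation"`.
#' @param min_size,max_size,n_perm,weight_exponent GSEA parameters, see
#'   [run_gsea()].
#' @param alpha combined-p gate (default 0.01).
#' @param overlap_threshold signature/perturbation overlap criterion
#'   (default 0.5).
#' @param weight Stouffer weight rule, see [combine_cohorts()].
#' @param seed top-level integer seed.
#' @return List with `gsea` (per-cohort result tables), `meta`, `gated`,
#'   `signatures`, `matches`, `down_regulators`, `cohort_summary`.
#' @export
run_analysis <- function(cohorts, motif_sets, perturbation_sets = NULL,
                         min_size = 15L, max_size = 500L, n_perm = 1000L,
                         weight_exponent = 1, alpha = 0.01,
                         overlap_threshold = 0.5, weight = "sqrt_n",
                         seed = 1L) {
  stopifnot(length(cohorts) >= 1L)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  results <- vector("list", length(cohorts))
  names(results) <- names(cohorts)
  for (i in seq_along(cohorts)) {
    results[[i]] <- run_gsea(cohorts[[i]], motif_sets,
                             min_size = min_size, max_size = max_size,
                             n_perm = n_perm,
                             weight_exponent = weight_exponent,
                             seed = (seed + i) %% .Machine$integer.max)
  }
  sizes <- vapply(cohorts, function(co) co$n_tn + co$n_er, 0)
  meta <- combine_cohorts(results, sizes, weight = weight)
  gated <- gate_and_rank(meta, alpha = alpha)
  signatures <- build_signatures(results, gated$set_name)
  matches <- NULL
  down <- NULL
  if (!is.null(perturbation_sets) && length(signatures) > 0L) {
    matches <- do.call(rbind, lapply(signatures, match_signature,
                                     collection = perturbation_sets,
                                     threshold = overlap_threshold))
    rownames(matches) <- NULL
    down <- report_down_regulators(matches)
  }
  list(gsea = results, meta = meta, gated = gated,
       signatures = signatures, matches = matches,
       down_regulators = down,
       cohort_summary = summarize_cohorts(cohorts))
}

#' Read a pipeline configuration file
#'
#' YAML with the fields used by [run_pipeline()]: a `cohorts` list
#' (each entry `name`, `expression`, `phenotypes`, `probe_map`,
#' `tn_pattern`, `er_pattern`), `motif_gmt`, `perturbation_gmt`, a
#' `gsea` block (`min_size`, `max_size`, `n_perm`, `weight_exponent`),
#' `alpha`, `overlap_threshold`, `weight`, `seed` and `out_dir`.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path path to a YAML config (e.g. written by
#'   [simulate_study()]).
#' @return The config as a list, with a `base_dir` element added.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}

#' Run the pipeline end to end from a configuration
#'
#' Reads every input, builds the cohorts, runs [run_analysis()], and
#' writes into the output directory: `table1.tsv` (gated sets with
#' per-cohort p-values and the combined Stouffer p), `table2.tsv`
#' (consensus signatures), `table3.tsv` (perturbation down-regulator
#' report), `cohort_summary.tsv`, per-cohort `gsea_<cohort>.tsv`, and a
#' `log.txt` recording the seed, parameters and per-stage counts.
#'
#' @param config a config list (see [read_pipeline_config()]) or a path
#'   to a YAML config file.
#' @return The [run_analysis()] result list, invisibly, with an
#'   `out_dir` element.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  base <- if (!is.null(config$base_dir)) config$base_dir else "."
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  stage <- "read gene sets"
  res <- tryCatch({
    motif <- read_gmt(rel(config$motif_gmt), kind = "motif")
    pert <- if (!is.null(config$perturbation_gmt))
      read_gmt(rel(config$perturbation_gmt), kind = "perturbation")
    stage <- "build cohorts"
    cohorts <- lapply(config$cohorts, function(e) {
      build_cohort(e$name,
                   read_expression(rel(e$expression)),
                   read_probe_map(rel(e$probe_map)),
                   read_phenotypes(rel(e$phenotypes)),
                   phenotype_patterns(e$tn_pattern, e$er_pattern))
    })
    names(cohorts) <- vapply(config$cohorts, `[[`, "", "name")
    stage <- "analysis"
    g <- config$gsea
    run_analysis(cohorts, motif, pert,
                 min_size = g$min_size %||% 15L,
                 max_size = g$max_size %||% 500L,
                 n_perm = g$n_perm %||% 1000L,
                 weight_exponent = g$weight_exponent %||% 1,
                 alpha = config$alpha %||% 0.01,
                 overlap_threshold = config$overlap_threshold %||% 0.5,
                 weight = config$weight %||% "sqrt_n",
                 seed = config$seed %||% 1L)
  }, error = function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                      stage, conditionMessage(e)),
                              call. = FALSE))
  out_dir <- config$out_dir %||% "results"
  if (!grepl("^(/|[A-Za-z]:)", out_dir)) out_dir <- file.path(base, out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_meta_table(res$gated, file.path(out_dir, "table1.tsv"))
  utils::write.table(signatures_table(res$signatures),
                     file.path(out_dir, "table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t3 <- if (!is.null(res$down_regulators))
    res$down_regulators[, c("set_name", "n_signatures", "detail")]
  else data.frame(set_name = character(), n_signatures = integer(),
                  detail = character())
  utils::write.table(t3, file.path(out_dir, "table3.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$cohort_summary,
                     file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (co in names(res$gsea))
    write_gsea_result(res$gsea[[co]],
                      file.path(out_dir, sprintf("gsea_%s.tsv", co)))
  log <- c(sprintf("seed: %s", config$seed %||% 1L),
           sprintf("gsea: min_size=%s max_size=%s n_perm=%s weight_exponent=%s",
                   config$gsea$min_size %||% 15L,
                   config$gsea$max_size %||% 500L,
                   config$gsea$n_perm %||% 1000L,
                   config$gsea$weight_exponent %||% 1),
           sprintf("alpha: %s  overlap_threshold: %s  weight: %s",
                   config$alpha %||% 0.01, config$overlap_threshold %||% 0.5,
                   config$weight %||% "sqrt_n"),
           sprintf("cohorts: %d (total n=%d)", length(res$gsea),
                   res$cohort_summary$n[res$cohort_summary$cohort == "TOTAL"]),
           sprintf("sets combined: %d, gated at alpha: %d, signatures: %d",
                   nrow(res$meta), nrow(res$gated), length(res$signatures)),
           sprintf("passing DN perturbation sets: %d",
                   if (is.null(res$down_regulators)) 0L
                   else nrow(res$down_regulators)))
  writeLines(log, file.path(out_dir, "log.txt"))
  res$out_dir <- out_dir
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Table-1-style wide TSV: set, one p column per cohort, combined stats.
write_meta_table <- function(meta, path) {
  cohorts <- sort(unique(unlist(lapply(meta$cohort_p, names))))
  wide <- data.frame(set_name = meta$set_name, stringsAsFactors = FALSE)
  for (co in cohorts)
    wide[[paste0("p_", co)]] <- vapply(meta$cohort_p, function(p)
      if (co %in% names(p)) p[[co]] else NA_real_, 0)
  wide$n_cohorts <- meta$n_cohorts
  wide$z_combined <- meta$z_combined
  wide$p_combined <- meta$p_combined
  wide$rank <- meta$rank
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-group expression comparison for a single gene
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of TN vs ER+
#' expression plus the display statistics used for box plots: per-arm
#' median and 10th/90th percentiles.
#'
#' @param cohort an `expression_cohort`.
#' @param gene gene symbol (uppercased for matching).
#' @return data.frame with one row: `gene`, `p_value`, `n_tn`, `n_er`,
#'   `median_tn`, `median_er`, `q10_tn`, `q90_tn`, `q10_er`, `q90_er`.
#' @export
compare_gene_expression <- function(cohort, gene) {
  gene <- toupper(gene)
  if (!gene %in% rownames(cohort$values))
    stop("gene not present in cohort: ", gene)
  x <- cohort$values[gene, ]
  tn <- x[cohort$labels == "TN"]
  er <- x[cohort$labels == "ERPOS"]
  if (length(tn) == 0L || length(er) == 0L) stop("both arms must be nonempty")
  p <- suppressWarnings(stats::wilcox.test(tn, er, exact = FALSE)$p.value)
  q <- function(v) stats::quantile(v, c(0.1, 0.9), names = FALSE)
  qt <- q(tn); qe <- q(er)
  data.frame(gene = gene, p_value = p,
             n_tn = length(tn), n_er = length(er),
             median_tn = stats::median(tn), median_er = stats::median(er),
             q10_tn = qt[1], q90_tn = qt[2],
             q10_er = qe[1], q90_er = qe[2],
             stringsAsFactors = FALSE)
}
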