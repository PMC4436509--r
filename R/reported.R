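#' Bundled reference tables from the seven-cohort breast-cancer screen
#'
#' The package ships, as plain TSV, the headline result tables of the
#' published seven-cohort triple-negative vs ER+/HER2- promoter-motif
#' screen this pipeline implements: per-cohort sample counts and IHC
#' patterns, the per-cohort GSEA p-values with the reported combined
#' Stouffer p per motif set, the consensus promoter-motif signatures,
#' and the perturbation-set overlap gene lists.  They serve as worked
#' inputs for [stouffer_weighted_z()] and [match_signature()] and as
#' regression fixtures; no external download is needed.
#'
#' @return `reported_cohorts()`: data.frame with `cohort`, `n_tn`,
#'   `n_er`, `tn_pattern`, `er_pattern`, `platform` (seven cohorts,
#'   2088 samples in total).
#' @name reported
NULL

reported_file <- function(name) {
  path <- system.file("extdata", name, package = "motifsig")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  path
}

#' @rdname reported
#' @export
reported_cohorts <- function() {
  utils::read.delim(reported_file("reported_cohorts.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reported
#' @return `reported_motif_pvalues()`: data.frame with `set_name`, one
#'   p-value column per cohort, and `reported_combined_p`.  The
#'   per-cohort values are printed to three decimals, so `0.000` cells
#'   are rounded displays of small permutation p-values, not literal
#'   zeros.
#' @export
reported_motif_pvalues <- function() {
  utils::read.delim(reported_file("reported_motif_pvalues.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reported
#' @return `reported_signatures()`: data.frame with `set_name`,
#'   `n_genes`, `n_cohorts` (the maximum cohort support) and the
#'   space-joined signature `genes`.
#' @export
reported_signatures <- function() {
  utils::read.delim(reported_file("reported_signatures.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reported
#' @return `reported_perturbation_overlaps()`: data.frame with
#'   `perturbation`, `cgp_set`, `signature` and the space-joined
#'   signature genes found in the perturbation's down-regulated set.
#' @export
reported_perturbation_overlaps <- function() {
  utils::read.delim(reported_file("reported_perturbation_overlaps.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
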