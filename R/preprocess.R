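#' Phenotype classification patterns
#'
#' A pair of 3-character patterns over the IHC code alphabet used to
#' assign each sample to the triple-negative (TN) or ER+/HER2- (ERPOS)
#' arm.  Position 1 is ER status, position 2 PR status, position 3 HER2
#' status.  `X` in a pattern matches any character at that position;
#' all other characters must match exactly (case-sensitively, so the
#' METABRIC dialect `"Nn1"` with its lowercase PR code and `1` = HER2-
#' works unchanged).
#'
#' @param tn_pattern pattern selecting TN samples, e.g. `"NNN"`.
#' @param er_pattern pattern selecting ER+/HER2- samples, e.g. `"PXN"`.
#' @return An object of class `phenotype_patterns`.
#' @examples
#' phenotype_patterns("NNN", "PXN")     # Affymetrix/DASL cohorts
#' phenotype_patterns("Nn1", "PX1")     # METABRIC dialect
#' @export
phenotype_patterns <- function(tn_pattern, er_pattern) {
  for (p in c(tn_pattern, er_pattern))
    if (!is.character(p) || length(p) != 1L || nchar(p) != 3L)
      stop("phenotype patterns must be single 3-character strings, got: ", p)
  structure(list(tn = tn_pattern, er = er_pattern),
            class = "phenotype_patterns")
}

code_matches <- function(codes, pattern) {
  pc <- strsplit(pattern, "")[[1L]]
  ok <- !is.na(codes) & nchar(codes) == 3L
  out <- rep(FALSE, length(codes))
  if (!any(ok)) return(out)
  cm <- do.call(rbind, strsplit(codes[ok], ""))
  hit <- rep(TRUE, nrow(cm))
  for (j in 1:3) if (pc[j] != "X") hit <- hit & cm[, j] == pc[j]
  out[ok] <- hit
  out
}

#' Classify samples into phenotype arms from IHC codes
#'
#' Samples matching the TN pattern are labelled `"TN"`, those matching
#' the ER+ pattern `"ERPOS"`, and everything else — including samples
#' with absent IHC metadata — `"EXCLUDED"`.  The TN pattern is tested
#' first; with the conventional disjoint pattern pairs (ER status N
#' vs P) the order never matters.
#'
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @param patterns a [phenotype_patterns] object.
#' @return Named character vector of labels (`TN`/`ERPOS`/`EXCLUDED`),
#'   one per sample, named by `sample_id`.
#' @export
classify_samples <- function(pheno, patterns) {
  stopifnot(inherits(patterns, "phenotype_patterns"))
  codes <- pheno$ihc_code
  lab <- rep("EXCLUDED", nrow(pheno))
  lab[code_matches(codes, patterns$er)] <- "ERPOS"
  lab[code_matches(codes, patterns$tn)] <- "TN"
  stats::setNames(lab, pheno$sample_id)
}

#' Collapse probe-level expression to gene level
#'
#' Withdrawn probes are dropped; remaining probes are grouped by gene
#' symbol and, for each gene and each sample independently, the gene's
#' value is the maximum over that gene's probes in that sample
#' (`per_sample_max`, the default).  This produces a chimeric per-gene
#' profile when different probes win in different samples; the
#' alternative `global_max_mean` picks, per gene, the single probe with
#' the highest mean expression across samples.
#'
#' @param values numeric matrix, probes x samples, probe ids as
#'   rownames.
#' @param map probe map data.frame from [read_probe_map()].  Every probe
#'   in `values` must have a map row.
#' @param collapse `"per_sample_max"` (default) or `"global_max_mean"`.
#' @return Numeric matrix, genes x samples, gene symbols as rownames.
#' @export
collapse_probes <- function(values, map,
                            collapse = c("per_sample_max", "global_max_mean")) {
  collapse <- match.arg(collapse)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  probes <- rownames(values)
  idx <- match(probes, map$probe_id)
  if (anyNA(idx))
    stop("probe(s) missing from map: ",
         paste(utils::head(probes[is.na(idx)], 10L), collapse = ", "))
  keep <- !map$withdrawn[idx]
  if (!any(keep)) stop("no probes survive withdrawn-identifier removal")
  values <- values[keep, , drop = FALSE]
  symbol <- map$symbol[idx][keep]
  groups <- split(seq_along(symbol), symbol)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(values),
                dimnames = list(names(groups), colnames(values)))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- values[rows, ]
    } else if (collapse == "per_sample_max") {
      out[g, ] <- do.call(pmax, lapply(rows, function(r) values[r, ]))
    } else {
      out[g, ] <- values[rows[which.max(rowMeans(values[rows, , drop = FALSE]))], ]
    }
  }
  out
}

#' Assemble an expression cohort
#'
#' Collapses probes to genes, classifies samples from IHC metadata, and
#' drops excluded samples, yielding the per-cohort object every
#' downstream stage consumes.  Samples present in the expression matrix
#' but absent from the phenotype table are treated as lacking metadata
#' and excluded.
#'
#' @param name cohort name.
#' @param raw probe-level matrix from [read_expression()].
#' @param map probe map from [read_probe_map()].
#' @param pheno phenotype table from [read_phenotypes()].
#' @param patterns a [phenotype_patterns] object.
#' @param collapse probe-collapse rule, see [collapse_probes()].
#' @return An `expression_cohort`: list with `name`, `values` (genes x
#'   retained samples), `labels` (`TN`/`ERPOS` per retained sample),
#'   `n_tn`, `n_er`, `n_excluded`.
#' @export
build_cohort <- function(name, raw, map, pheno, patterns,
                         collapse = "per_sample_max") {
  values <- collapse_probes(raw, map, collapse = collapse)
  lab <- rep("EXCLUDED", ncol(values))
  names(lab) <- colnames(values)
  known <- classify_samples(pheno, patterns)
  hit <- intersect(names(lab), names(known))
  lab[hit] <- known[hit]
  keep <- lab != "EXCLUDED"
  n_tn <- sum(lab == "TN")
  n_er <- sum(lab == "ERPOS")
  if (n_tn == 0L || n_er == 0L)
    stop(sprintf("cohort %s: empty arm after classification (TN=%d, ER+=%d)",
                 name, n_tn, n_er))
  structure(list(name = name,
                 values = values[, keep, drop = FALSE],
                 labels = lab[keep],
                 n_tn = n_tn, n_er = n_er,
                 n_excluded = sum(!keep)),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %s: %d genes, n=%d (TN=%d / ER+=%d, %d excluded)\n",
              x$name, nrow(x$values), x$n_tn + x$n_er, x$n_tn, x$n_er,
              x$n_excluded))
  invisible(x)
}

#' Summarize cohort sample counts
#'
#' Per-cohort `n`, `n_tn`, `n_er` plus a `TOTAL` row.  Accepts either a
#' list of `expression_cohort` objects or a data.frame that already has
#' `cohort`, `n_tn` and `n_er` columns (e.g. [reported_cohorts()]).
#'
#' @param cohorts list of cohorts or a data.frame.
#' @return data.frame with columns `cohort`, `n`, `n_tn`, `n_er`.
#' @export
summarize_cohorts <- function(cohorts) {
  if (is.data.frame(cohorts)) {
    df <- data.frame(cohort = cohorts$cohort,
                     n = as.integer(cohorts$n_tn + cohorts$n_er),
                     n_tn = as.integer(cohorts$n_tn),
                     n_er = as.integer(cohorts$n_er),
                     stringsAsFactors = FALSE)
  } else {
    stopifnot(length(cohorts) >= 1L)
    df <- do.call(rbind, lapply(cohorts, function(co) {
      stopifnot(inherits(co, "expression_cohort"))
      data.frame(cohort = co$name, n = as.integer(co$n_tn + co$n_er),
                 n_tn = as.integer(co$n_tn), n_er = as.integer(co$n_er),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(df, data.frame(cohort = "TOTAL", n = sum(df$n),
                       n_tn = sum(df$n_tn), n_er = sum(df$n_er)))
}
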