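#' Stouffer weighted-Z combination of p-values
#'
#' Converts one-sided p-values to normal quantiles
#' `z_i = qnorm(1 - p_i)`, combines them as
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` and maps back to a one-sided
#' p-value `1 - pnorm(Z)`.  The combination is invariant to rescaling
#' all weights by a positive constant.
#'
#' @param pvalues numeric vector of one-sided p-values in (0, 1).
#' @param weights positive weights, recycled length-1 allowed; default
#'   equal weights.
#' @param clip optional length-2 vector `(lo, hi)`: p-values are clipped
#'   into `[lo, hi]` before the quantile transform.  Used to keep
#'   permutation p-values (granular, bounded away from 0 by add-one
#'   smoothing) and rounded published values finite on the Z scale.
#' @return List with `z` and `p`.
#' @examples
#' stouffer_weighted_z(c(0.05, 0.05))           # ~0.010
#' stouffer_weighted_z(c(0.01), weights = 3)    # weights cancel for k = 1
#' @export
stouffer_weighted_z <- function(pvalues, weights = NULL, clip = NULL) {
  k <- length(pvalues)
  stopifnot(k >= 1L)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) == 1L) weights <- rep(weights, k)
  if (length(weights) != k) stop("weights must match pvalues in length")
  if (any(weights <= 0) || anyNA(weights)) stop("weights must be positive")
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] > 0, clip[2] < 1)
    pvalues <- pmin(pmax(pvalues, clip[1]), clip[2])
  }
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues >= 1))
    stop("p-values must lie strictly inside (0, 1) after clipping")
  z <- stats::qnorm(1 - pvalues)
  zc <- sum(weights * z) / sqrt(sum(weights^2))
  list(z = zc, p = 1 - stats::pnorm(zc))
}

#' Combine per-cohort enrichment p-values across cohorts
#'
#' For every gene set that is TN-enriched (positive ES) in at least one
#' cohort, the available per-cohort nominal p-values are combined with
#' [stouffer_weighted_z()] using sample-size weights
#' `w_i = sqrt(n_i)` (or `w_i = n_i`).  Cohorts where a set was
#' filtered, absent, or ER-enriched contribute nothing; the weights of
#' the remaining cohorts are renormalized implicitly by the Stouffer
#' denominator.  Each cohort's p-values are clipped to
#' `[1/(n_perm+1), 1 - 1/(n_perm+1)]` before the quantile transform.
#'
#' @param results named list, cohort name -> [run_gsea()] data.frame.
#' @param cohort_sizes named numeric vector of per-cohort sample counts
#'   `n = n_TN + n_ER`, names matching `names(results)`.
#' @param weight `"sqrt_n"` (default) or `"n"`.
#' @return data.frame ranked by ascending combined p (ties broken by set
#'   name): `set_name`, `n_cohorts`, `z_combined`, `p_combined`, `rank`,
#'   plus list-columns `cohort_p` and `cohort_weights` (named per
#'   cohort).
#' @export
combine_cohorts <- function(results, cohort_sizes,
                            weight = c("sqrt_n", "n")) {
  weight <- match.arg(weight)
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  if (!all(names(results) %in% names(cohort_sizes)))
    stop("cohort_sizes missing entries for: ",
         paste(setdiff(names(results), names(cohort_sizes)), collapse = ", "))
  cohorts <- sort(names(results))
  per <- lapply(cohorts, function(co) {
    df <- results[[co]]
    df <- df[df$direction == "TN_enriched", , drop = FALSE]
    list(p = stats::setNames(df$p_nominal, df$set_name),
         n_perm = if (nrow(df) > 0L) df$n_perm[1L] else NA_integer_)
  })
  names(per) <- cohorts
  all_sets <- sort(unique(unlist(lapply(per, function(x) names(x$p)))))
  if (length(all_sets) == 0L)
    return(data.frame(set_name = character(), n_cohorts = integer(),
                      z_combined = numeric(), p_combined = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  rows <- lapply(all_sets, function(s) {
    have <- cohorts[vapply(per, function(x) s %in% names(x$p), TRUE)]
    p <- vapply(have, function(co) per[[co]]$p[[s]], 0)
    w <- switch(weight, sqrt_n = sqrt(cohort_sizes[have]),
                n = cohort_sizes[have])
    eps <- 1 / (vapply(have, function(co) as.numeric(per[[co]]$n_perm), 0) + 1)
    pc <- pmin(pmax(p, eps), 1 - eps)
    st <- stouffer_weighted_z(pc, weights = w)
    list(set_name = s, n_cohorts = length(have), z = st$z, p = st$p,
         cohort_p = stats::setNames(p, have),
         cohort_w = stats::setNames(unname(w), have))
  })
  out <- data.frame(set_name = vapply(rows, `[[`, "", "set_name"),
                    n_cohorts = vapply(rows, `[[`, 0L, "n_cohorts"),
                    z_combined = vapply(rows, `[[`, 0, "z"),
                    p_combined = vapply(rows, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$cohort_p <- lapply(rows, `[[`, "cohort_p")
  out$cohort_weights <- lapply(rows, `[[`, "cohort_w")
  out <- out[order(out$p_combined, out$set_name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gate combined results at a significance threshold
#'
#' Retains sets with `p_combined < alpha` (strict, the published gate
#' is "p < .01"), preserving rank order.
#'
#' @param meta data.frame from [combine_cohorts()].
#' @param alpha significance gate in (0, 1); default 0.01.
#' @return The gated subset of `meta`.
#' @export
gate_and_rank <- function(meta, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  out <- meta[meta$p_combined < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus signature for one gene set
#'
#' Counts, for every gene in the union of the per-cohort leading edges,
#' the number of cohorts whose leading edge contains it, and keeps the
#' genes attaining the maximum count.  These maximally-supported genes
#' are the promoter-motif signature.
#'
#' @param set_name set identifier.
#' @param leading_edges named list, cohort -> character vector of
#'   leading-edge genes for this set (empty vectors allowed; cohorts
#'   where the set was absent should simply be omitted).
#' @return Object of class `consensus_signature`: list with `set_name`,
#'   `support_counts` (named integer over the union), `max_support`,
#'   `n_cohorts` and `genes` (lexicographically sorted genes at maximum
#'   support).
#' @examples
#' consensus_signature("S", list(c1 = c("A", "B"), c2 = c("B", "C")))$genes
#' @export
consensus_signature <- function(set_name, leading_edges) {
  stopifnot(is.list(leading_edges), length(leading_edges) >= 1L)
  edges <- lapply(leading_edges, unique)
  if (all(lengths(edges) == 0L))
    stop("all leading edges are empty for set ", set_name)
  counts <- table(unlist(edges, use.names = FALSE))
  support <- stats::setNames(as.integer(counts), names(counts))
  support <- support[order(names(support), method = "radix")]
  max_support <- max(support)
  structure(list(set_name = set_name,
                 support_counts = support,
                 max_support = max_support,
                 n_cohorts = length(leading_edges),
                 genes = sort(names(support)[support == max_support],
                              method = "radix")),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("<consensus_signature> %s: %d gene(s) in %d of %d cohorts\n  [%s]\n",
              x$set_name, length(x$genes), x$max_support, x$n_cohorts,
              paste(x$genes, collapse = " ")))
  invisible(x)
}

#' Build consensus signatures for the gated sets
#'
#' For each named set, gathers the leading edges of its TN-enriched
#' per-cohort results and calls [consensus_signature()].  Support is
#' counted over every cohort in which the set produced a TN-enriched
#' leading edge, whether or not that cohort's individual p-value was
#' small.
#'
#' @param results named list, cohort -> [run_gsea()] data.frame.
#' @param set_names character vector (normally
#'   `gate_and_rank(...)$set_name`).
#' @return Named list of `consensus_signature` objects.
#' @export
build_signatures <- function(results, set_names) {
  sigs <- lapply(set_names, function(s) {
    edges <- list()
    for (co in names(results)) {
      df <- results[[co]]
      i <- which(df$set_name == s & df$direction == "TN_enriched")
      if (length(i) == 1L && length(df$leading_edge[[i]]) > 0L)
        edges[[co]] <- df$leading_edge[[i]]
    }
    if (length(edges) == 0L) return(NULL)
    consensus_signature(s, edges)
  })
  names(sigs) <- set_names
  sigs[!vapply(sigs, is.null, TRUE)]
}

#' Tabulate consensus signatures
#'
#' One row per signature: set name, number of signature genes, the
#' maximum cohort-support count, and the space-joined gene list —
#' sorted by support then by gene count, both descending.
#'
#' @param signatures named list from [build_signatures()].
#' @return data.frame with columns `set_name`, `n_genes`, `n_cohorts`,
#'   `genes`.
#' @export
signatures_table <- function(signatures) {
  if (length(signatures) == 0L)
    return(data.frame(set_name = character(), n_genes = integer(),
                      n_cohorts = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(signatures, function(s) {
    data.frame(set_name = s$set_name, n_genes = length(s$genes),
               n_cohorts = s$max_support,
               genes = paste(s$genes, collapse = " "),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$n_cohorts, -df$n_genes, df$set_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}
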