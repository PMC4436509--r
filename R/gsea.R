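#' Signal-to-noise ranking metric
#'
#' The two-class default ranking statistic: for each gene,
#' `(mu_TN - mu_ER) / (sd_TN' + sd_ER')` where each arm's standard
#' deviation is floored at `sd' = max(sd, 0.2 * |mu|, 0.2)` so genes
#' with (near-)constant expression in an arm cannot produce unbounded
#' scores.  Positive values mean higher expression in TN.
#'
#' @param cohort an `expression_cohort` from [build_cohort()], or any
#'   list with a genes x samples `values` matrix and a `labels` vector
#'   over `TN`/`ERPOS`.
#' @param labels optional label vector overriding `cohort$labels`
#'   (used internally by the permutation test).
#' @return Named numeric vector, one finite score per gene.
#' @export
signal_to_noise <- function(cohort, labels = NULL) {
  x <- cohort$values
  lab <- if (is.null(labels)) cohort$labels else labels
  i1 <- which(lab == "TN")
  i2 <- which(lab == "ERPOS")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("signal-to-noise needs >= 2 samples per arm ",
         "(gene-permutation mode is not supported)")
  .s2n(x, i1, i2)
}

# core metric on column index sets; shared with the permutation loop
.s2n <- function(x, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- sqrt(rowSums((x1 - m1)^2) / (n1 - 1L))
  s2 <- sqrt(rowSums((x2 - m2)^2) / (n2 - 1L))
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
  (m1 - m2) / (s1 + s2)
}

#' Rank genes by a metric
#'
#' Sorts descending; ties in the metric are broken by gene symbol
#' (lexicographic, C locale) so rankings are deterministic.
#'
#' @param metric named numeric vector.
#' @return The same vector, sorted into ranking order.
#' @export
rank_genes <- function(metric) {
  stopifnot(!is.null(names(metric)))
  metric[order(-metric, names(metric), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at each gene in the set ("hit") the running
#' sum increases by `|metric|^w / sum_set(|metric|^w)`, at each miss it
#' decreases by `1 / (N - N_hit)`.  The enrichment score (ES) is the
#' signed maximum deviation of this walk from zero.  The leading edge is
#' the set genes at or before the maximum (ES > 0) or at or after the
#' minimum (ES < 0).  If every set member has metric 0 (so the weighted
#' increments are undefined) hits fall back to equal weights.
#'
#' @param ranked named metric vector already in ranking order (see
#'   [rank_genes()]).
#' @param genes character vector of set member symbols.
#' @param weight_exponent KS weight exponent `w`; 1 is the classical
#'   weighted statistic, 0 the unweighted KS.
#' @return List with `es`, `running_sum` (length N), `leading_edge`,
#'   `hit_positions` and `n_hit`.
#' @export
enrichment_score <- function(ranked, genes, weight_exponent = 1) {
  nm <- names(ranked)
  N <- length(ranked)
  hit <- nm %in% genes
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no overlap with the ranked list")
  if (n_hit == N) stop("gene set covers the whole ranked list (no misses)")
  w <- abs(ranked[hit])^weight_exponent
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, n_hit); nr <- n_hit }
  inc <- rep(-1 / (N - n_hit), N)
  inc[hit] <- w / nr
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= abs(running[i_min])) running[i_max]
        else running[i_min]
  pos <- which(hit)
  le <- if (es > 0) nm[pos[pos <= i_max]]
        else if (es < 0) nm[pos[pos >= i_min]]
        else character()
  list(es = unname(es), running_sum = unname(running), leading_edge = le,
       hit_positions = pos, n_hit = n_hit)
}

# ES from sorted hit positions only: O(k) instead of O(N), used inside
# the permutation loop.  `wts` are |metric|^w at the hit positions.
.es_from_positions <- function(pos, wts, N) {
  k <- length(pos)
  nr <- sum(wts)
  if (nr == 0) { wts <- rep(1, k); nr <- k }
  cumw <- cumsum(wts) / nr
  miss <- (pos - seq_len(k)) / (N - k)
  dev_at_hit <- cumw - miss            # walk value at each hit
  dev_before <- c(0, cumw[-k]) - miss  # walk value just before each hit
  hi <- max(dev_at_hit)
  lo <- min(dev_before, 0)
  if (hi >= abs(lo)) hi else lo
}

#' Phenotype-permutation GSEA for one cohort
#'
#' Computes, per gene set: the observed enrichment score, a
#' phenotype-permutation null (sample labels permuted preserving arm
#' sizes; the signal-to-noise ranking and every retained set's ES
#' recomputed per permutation), a sign-aware nominal p-value with
#' add-one smoothing `p = (b + 1) / (m + 1)` where `m` counts
#' permutations whose ES has the observed sign and `b` those at least as
#' extreme, the normalized enrichment score
#' `NES = ES / mean(|permuted ES| of the same sign)` (`NA` if no
#' same-sign permutation exists), and the leading-edge genes.
#'
#' Sets are intersected with the cohort's genes and then filtered by
#' size; filtered or non-overlapping sets are reported via `message()`
#' and omitted from the result.
#'
#' @param cohort an `expression_cohort`.
#' @param collection a [gene_set_collection] (normally kind `"motif"`).
#' @param min_size,max_size set-size filter applied after intersection
#'   with the cohort's genes (GSEA defaults 15 and 500).
#' @param n_perm number of label permutations (default 1000).
#' @param weight_exponent KS weight exponent (default 1).
#' @param seed integer seed for the permutation stream; the RNG state of
#'   the caller is restored on exit.  `NULL` continues the current
#'   stream.
#' @return data.frame with one row per retained set: `set_name`, `size`,
#'   `es`, `nes`, `p_nominal`, `n_perm`, `n_perm_same_sign`, `direction`
#'   (`TN_enriched`/`ER_enriched`), and a list-column `leading_edge`.
#'   Rows are ordered by `p_nominal` (ties by set name).
#' @export
run_gsea <- function(cohort, collection, min_size = 15L, max_size = 500L,
                     n_perm = 1000L, weight_exponent = 1, seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"), n_perm >= 1L)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  genes <- rownames(cohort$values)
  if (length(collection) == 0L)
    return(.empty_gsea_result())
  present <- lapply(collection$sets, intersect, x = genes)
  sz <- lengths(present)
  keep <- sz >= min_size & sz <= max_size
  if (any(!keep))
    message(sprintf("%d of %d sets filtered (overlap size outside [%d, %d]): %s",
                    sum(!keep), length(keep), min_size, max_size,
                    paste(utils::head(names(collection)[!keep], 8L),
                          collapse = ", ")))
  if (!any(keep)) return(.empty_gsea_result())
  sets <- present[keep]
  set_names <- names(sets)

  ranked <- rank_genes(signal_to_noise(cohort))
  obs <- lapply(sets, enrichment_score, ranked = ranked,
                weight_exponent = weight_exponent)
  es_obs <- vapply(obs, `[[`, 0, "es")

  # shared permutation stream: one ranking per permutation, all sets
  # scored on it
  x <- cohort$values
  lab <- cohort$labels
  N <- nrow(x)
  set_idx <- lapply(sets, match, table = genes)
  es_perm <- matrix(NA_real_, nrow = length(sets), ncol = n_perm)
  for (b in seq_len(n_perm)) {
    pl <- sample(lab)
    met <- .s2n(x, which(pl == "TN"), which(pl == "ERPOS"))
    ord <- order(-met, genes, method = "radix")
    rk <- integer(N); rk[ord] <- seq_len(N)
    met_abs_w <- abs(met)^weight_exponent
    for (s in seq_along(sets)) {
      p <- sort(rk[set_idx[[s]]])
      es_perm[s, b] <- .es_from_positions(p, met_abs_w[ord[p]], N)
    }
  }

  p_nom <- nes <- rep(NA_real_, length(sets))
  m_same <- integer(length(sets))
  for (s in seq_along(sets)) {
    same <- if (es_obs[s] >= 0) es_perm[s, ] >= 0 else es_perm[s, ] < 0
    m <- sum(same)
    m_same[s] <- m
    b <- sum(abs(es_perm[s, same]) >= abs(es_obs[s]))
    p_nom[s] <- (b + 1) / (m + 1)
    nes[s] <- if (m > 0) es_obs[s] / mean(abs(es_perm[s, same])) else NA_real_
  }

  out <- data.frame(set_name = set_names,
                    size = unname(lengths(sets)),
                    es = unname(es_obs),
                    nes = unname(nes),
                    p_nominal = unname(p_nom),
                    n_perm = n_perm,
                    n_perm_same_sign = unname(m_same),
                    direction = ifelse(es_obs >= 0, "TN_enriched",
                                       "ER_enriched"),
                    stringsAsFactors = FALSE)
  out$leading_edge <- unname(lapply(obs, `[[`, "leading_edge"))
  out <- out[order(out$p_nominal, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_gsea_result <- function() {
  out <- data.frame(set_name = character(), size = integer(),
                    es = numeric(), nes = numeric(), p_nominal = numeric(),
                    n_perm = integer(), n_perm_same_sign = integer(),
                    direction = character(), stringsAsFactors = FALSE)
  out$leading_edge <- list()
  out
}

#' Permutation null for a single gene set
#'
#' Convenience wrapper around [run_gsea()] for one explicit gene vector
#' with no size filtering.
#'
#' @param cohort an `expression_cohort`.
#' @param genes character vector of set members.
#' @param n_perm,weight_exponent,seed as in [run_gsea()].
#' @return List with `es`, `nes`, `p_nominal`, `n_perm_same_sign`,
#'   `leading_edge`.
#' @export
permutation_null <- function(cohort, genes, n_perm = 1000L,
                             weight_exponent = 1, seed = NULL) {
  coll <- gene_set_collection(list(SET = genes), kind = "motif")
  res <- run_gsea(cohort, coll, min_size = 1L, max_size = .Machine$integer.max,
                  n_perm = n_perm, weight_exponent = weight_exponent,
                  seed = seed)
  if (nrow(res) == 0L) stop("gene set has no overlap with the cohort")
  list(es = res$es, nes = res$nes, p_nominal = res$p_nominal,
       n_perm_same_sign = res$n_perm_same_sign,
       leading_edge = res$leading_edge[[1L]])
}

#' Write a per-cohort enrichment table
#'
#' TSV with `set_name`, `size`, `es`, `nes`, `p_nominal`, `direction`
#' and the comma-joined leading edge.
#'
#' @param result data.frame from [run_gsea()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gsea_result <- function(result, path) {
  flat <- result
  flat$leading_edge <- vapply(result$leading_edge, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
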