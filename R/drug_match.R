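#' Match a consensus signature against perturbation gene sets
#'
#' For every set in a perturbation collection, computes the overlap with
#' the signature and the overlap fraction
#' `|signature inter set| / |signature|` — the denominator is the
#' signature size, so the criterion reads "at least `threshold` of the
#' signature's genes are found in the perturbation set".  The
#' perturbation direction is parsed from the MSigDB-style `_DN` / `_UP`
#' name suffix; sets without a suffix are recorded with direction
#' `"unknown"` and never appear in down-regulator reports.
#'
#' @param sig a `consensus_signature` or a character vector of signature
#'   genes (a `signature_name` attribute or name can accompany the
#'   latter via `signature_name`).
#' @param collection a [gene_set_collection] of kind `"perturbation"`.
#' @param threshold passing overlap fraction, inclusive (default 0.5:
#'   exactly half the signature passes).
#' @param signature_name name used when `sig` is a bare gene vector.
#' @return data.frame sorted by decreasing overlap fraction (ties by set
#'   name): `signature_name`, `set_name`, `direction`, `n_overlap`,
#'   `overlap_fraction`, `passes`, plus a list-column `overlap_genes`.
#' @export
match_signature <- function(sig, collection, threshold = 0.5,
                            signature_name = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (collection$kind != "perturbation")
    stop("collection kind must be 'perturbation'")
  stopifnot(threshold > 0, threshold <= 1)
  if (inherits(sig, "consensus_signature")) {
    genes <- sig$genes
    if (is.null(signature_name)) signature_name <- sig$set_name
  } else {
    genes <- unique(toupper(as.character(sig)))
    if (is.null(signature_name)) signature_name <- "signature"
  }
  if (length(genes) == 0L) stop("empty signature")
  nm <- names(collection)
  direction <- rep("unknown", length(nm))
  direction[grepl("_DN$", nm)] <- "DN"
  direction[grepl("_UP$", nm)] <- "UP"
  ov <- lapply(collection$sets, function(s) sort(intersect(genes, s)))
  frac <- lengths(ov) / length(genes)
  out <- data.frame(signature_name = signature_name,
                    set_name = nm,
                    direction = direction,
                    n_overlap = unname(lengths(ov)),
                    overlap_fraction = unname(frac),
                    passes = unname(frac >= threshold),
                    stringsAsFactors = FALSE)
  out$overlap_genes <- unname(ov)
  out <- out[order(-out$overlap_fraction, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report perturbations that down-regulate signatures
#'
#' Filters matches to passing `_DN` sets and groups them by perturbation
#' set, listing for each the signatures it covers and the signature
#' genes found in it.
#'
#' @param matches data.frame from one or more [match_signature()] calls
#'   (row-bind them to screen several signatures at once).
#' @return data.frame with one row per passing `_DN` perturbation set:
#'   `set_name`, `n_signatures`, `signatures` (comma-joined), `detail`
#'   (one `SIG = [genes]` clause per covered signature), plus
#'   list-columns `signature_names` and `genes_found`.
#' @export
report_down_regulators <- function(matches) {
  keep <- matches[matches$direction == "DN" & matches$passes, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(set_name = character(), n_signatures = integer(),
                      signatures = character(), detail = character(),
                      stringsAsFactors = FALSE))
  groups <- split(seq_len(nrow(keep)), keep$set_name)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    i <- i[order(keep$signature_name[i])]
    clauses <- vapply(i, function(j)
      sprintf("%s = [%s]", keep$signature_name[j],
              paste(keep$overlap_genes[[j]], collapse = " ")), "")
    out <- data.frame(set_name = g, n_signatures = length(i),
                      signatures = paste(keep$signature_name[i],
                                         collapse = ","),
                      detail = paste(clauses, collapse = " "),
                      stringsAsFactors = FALSE)
    out$signature_names <- list(keep$signature_name[i])
    out$genes_found <- list(stats::setNames(keep$overlap_genes[i],
                                            keep$signature_name[i]))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_signatures, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
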