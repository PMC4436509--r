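#' Gene set collections
#'
#' A `gene_set_collection` holds named gene sets of one of two kinds:
#' `"motif"` (transcription-factor promoter-motif target sets, the
#' screening collection) or `"perturbation"` (chemical/genetic
#' perturbation response sets, conventionally suffixed `_UP`/`_DN`).
#' Gene symbols are stored uppercased so all downstream comparisons are
#' case-insensitive.
#'
#' @param sets named list of character vectors of gene symbols.  Names
#'   are the set identifiers (e.g. `"V$HIF1_Q5"`); symbols are
#'   uppercased and de-duplicated.
#' @param kind `"motif"` or `"perturbation"`.
#' @param descriptions optional character vector of free-text
#'   descriptions, one per set (recycled `"na"` when missing).
#' @return An object of class `gene_set_collection`: a list with
#'   elements `sets`, `descriptions` and `kind`.
#' @examples
#' gene_set_collection(list(SET_A = c("TP53", "MYC")), kind = "motif")
#' @export
gene_set_collection <- function(sets, kind = c("motif", "perturbation"),
                                descriptions = NULL) {
  kind <- match.arg(kind)
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  nm <- names(sets)
  if (length(sets) > 0L && (is.null(nm) || any(!nzchar(nm))))
    stop("every gene set must have a nonempty name")
  if (anyDuplicated(nm))
    stop("duplicate gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- toupper(as.character(g))
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L))
    stop("gene sets must be nonempty: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets))
    stop("`descriptions` must have one entry per set")
  names(descriptions) <- nm
  structure(list(sets = sets, descriptions = descriptions, kind = kind),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> kind=%s, %d sets\n", x$kind, length(x)))
  if (length(x) > 0L) {
    show <- utils::head(names(x), 5L)
    cat("  ", paste(sprintf("%s (%d)", show, lengths(x$sets[show])),
                    collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the MSigDB GMT dialect: one set per line,
#' `name TAB description TAB gene TAB gene ...`.  Symbols are
#' uppercased; duplicate symbols within a line are dropped with a
#' warning; lines with fewer than three fields are an error.  Order of
#' sets and of genes within a set is preserved as listed.
#'
#' @param path path to a GMT file.
#' @param kind collection kind, `"motif"` or `"perturbation"`.
#' @return A [gene_set_collection].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path, kind = c("motif", "perturbation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(gene_set_collection(stats::setNames(list(), character()), kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    g <- toupper(fields[[i]][-(1:2)])
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning(sprintf("line %d (%s): %d duplicate gene symbol(s) dropped",
                      i, nm[i], sum(duplicated(g))))
      g <- unique(g)
    }
    sets[[i]] <- g
  }
  names(sets) <- nm
  gene_set_collection(sets, kind = kind, descriptions = desc)
}

#' Write a GMT gene-set file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x))` reproduces `x`
#' exactly.  Tabs, carriage returns and newlines inside descriptions
#' would corrupt the format, so they are replaced by single spaces;
#' empty descriptions are written as `"na"`.
#'
#' @param collection a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- gsub("[\t\r\n]+", " ", collection$descriptions)
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], desc[i], collection$sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
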