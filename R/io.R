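#' Read a tab-separated expression matrix
#'
#' File dialect: probes (or genes) as rows, samples as columns.  The
#' first column holds the probe/gene identifier; the first row holds
#' sample identifiers.  Values are assumed already normalized on
#' whatever scale the upstream platform produced.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix with probe ids as rownames and sample ids
#'   as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate probe/gene ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  if (any(!nzchar(ids)) || anyNA(ids)) stop("missing probe/gene id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Write an expression matrix in the dialect read_expression() expects
#'
#' @param values numeric matrix, probes x samples, with dimnames.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, id_column = "probe_id") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype (IHC metadata) table
#'
#' Two tab-separated columns, `sample_id` and `ihc_code`.  The code is a
#' 3-character ER/PR/HER2 status string (e.g. `"NNN"`, `"PPN"`,
#' METABRIC-style `"Nn1"`).  A missing or empty code is kept as `NA`:
#' samples lacking IHC metadata are retained at parse time and excluded
#' only downstream by [classify_samples()].
#'
#' @param path path to a TSV file with a header row.
#' @return A data.frame with character columns `sample_id` and
#'   `ihc_code` (`NA` when absent).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("sample_id", "ihc_code") %in% colnames(df)))
    stop("phenotype file must have columns sample_id, ihc_code")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in phenotype table")
  df[, c("sample_id", "ihc_code")]
}

#' Write a phenotype table
#' @param pheno data.frame with columns `sample_id`, `ihc_code`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(all(c("sample_id", "ihc_code") %in% colnames(pheno)))
  utils::write.table(pheno[, c("sample_id", "ihc_code")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe-to-symbol map
#'
#' Three tab-separated columns: `probe_id`, `accession` (platform
#' accession or UniGene id) and `symbol` (the HUGO recommended gene
#' name).  Probes whose identifier has been withdrawn from the
#' annotation carry the literal token `WITHDRAWN` in the symbol column;
#' they are parsed and flagged here and removed by [collapse_probes()].
#'
#' @param path path to a TSV file with a header row.
#' @return A data.frame with columns `probe_id`, `accession`, `symbol`
#'   (uppercased) and logical `withdrawn`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "accession", "symbol") %in% colnames(df)))
    stop("probe map must have columns probe_id, accession, symbol")
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in probe map")
  df$symbol <- toupper(df$symbol)
  df$withdrawn <- df$symbol == "WITHDRAWN"
  df[, c("probe_id", "accession", "symbol", "withdrawn")]
}

#' Write a probe map
#' @param map data.frame with columns `probe_id`, `accession`, `symbol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(map, path) {
  stopifnot(all(c("probe_id", "accession", "symbol") %in% colnames(map)))
  utils::write.table(map[, c("probe_id", "accession", "symbol")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
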