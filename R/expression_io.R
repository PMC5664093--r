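#' Read a probe-by-sample expression matrix from TSV
#'
#' Expects a tab-separated text file whose first row holds sample identifiers,
#' whose first column holds probe identifiers, and whose remaining cells are
#' numeric signal values. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return An `expression_matrix` object: a numeric matrix with probe ids as
#'   rownames and sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs a probe column and >= 1 sample column")
  probe_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) | raw == "", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("missing or non-numeric value at probe '%s', sample '%s' (cell '%s')",
                 probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 raw[bad[1L, 1L], bad[1L, 2L]]))
  }
  expression_matrix(vals, probe_ids, sample_ids)
}

#' Construct a validated expression matrix
#'
#' @param values Numeric probe-by-sample matrix.
#' @param probe_ids,sample_ids Unique identifier vectors matching the matrix
#'   dimensions.
#' @return An `expression_matrix` (numeric matrix with dimnames and class tag).
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values))
    stop("probe_ids length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyNA(values)) stop("missing values are not allowed in an expression matrix")
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Write an expression matrix to TSV at full precision
#'
#' @param m An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(probe_id = rownames(m),
                   format(unclass(m), digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group assignments
#'
#' TSV with columns `sample_id` and `group`; exactly two distinct group labels
#' are required, both non-empty.
#'
#' @param path Path to the metadata TSV.
#' @return Named character vector mapping sample id to group label.
#' @export
read_sample_groups <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("sample metadata needs columns 'sample_id' and 'group'")
  sample_groups(stats::setNames(tab$group, tab$sample_id))
}

#' Validate a sample-to-group assignment
#'
#' @param assignments Named character vector (names = sample ids, values =
#'   group labels); exactly two distinct labels.
#' @return The validated named vector.
#' @export
sample_groups <- function(assignments) {
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    stop("group assignments must be named by sample id")
  if (anyDuplicated(names(assignments))) stop("duplicate sample id in group assignments")
  labs <- unique(assignments)
  if (length(labs) != 2L)
    stop("exactly two group labels required, got: ", paste(labs, collapse = ", "))
  assignments
}

#' Column z-normalize an expression matrix
#'
#' Each sample column is centred to mean 0 and scaled to sample standard
#' deviation 1 (n-1 denominator), matching per-sample `scale()` normalization.
#'
#' @param m An `expression_matrix`.
#' @return The normalized `expression_matrix`.
#' @export
normalize_samples <- function(m) {
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(unclass(m), center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  expression_matrix(z, rownames(m), colnames(m))
}

#' Read a probe-to-gene mapping table
#'
#' TSV with columns `probe_id` and `gene_symbol`; a probe may map to several
#' symbols on repeated rows.
#'
#' @param path Path to the mapping TSV.
#' @return A data.frame with columns `probe_id`, `gene_symbol` (unique pairs).
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% colnames(tab)))
    stop("probe map needs columns 'probe_id' and 'gene_symbol'")
  unique(tab[, c("probe_id", "gene_symbol")])
}

#' Map probe ids to gene symbols
#'
#' Expands each probe through the mapping (one probe may yield several
#' symbols), de-duplicates while preserving first-appearance order, and
#' reports unmapped probes instead of dropping them silently.
#'
#' @param probes Character vector of probe ids.
#' @param map Data.frame with columns `probe_id`, `gene_symbol`.
#' @return List with `genes` (unique symbols in first-appearance order) and
#'   `unmapped` (probes absent from the map).
#' @export
map_probes <- function(probes, map) {
  stopifnot(is.data.frame(map), all(c("probe_id", "gene_symbol") %in% colnames(map)))
  probes <- as.character(probes)
  hits <- map[map$probe_id %in% probes, , drop = FALSE]
  # keep first-appearance order of the *query* probes, then map row order
  hits <- hits[order(match(hits$probe_id, probes)), , drop = FALSE]
  genes <- unique(hits$gene_symbol)
  unmapped <- setdiff(probes, map$probe_id)
  list(genes = genes, unmapped = unmapped)
}
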