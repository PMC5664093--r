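#' Read a gene-set collection from a GMT file
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (gene symbols per set).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT file")
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = rep("na", length(sets))) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' For each set, computes the one-sided hypergeometric upper-tail probability
#' of the observed overlap between the query and the set, given the
#' background universe (Fisher mode). EASE mode conservatively reduces the
#' observed overlap by one before computing the tail (overlap 0 after the
#' reduction gives p = 1). P-values are BH-adjusted across sets.
#'
#' Symbols are matched case-insensitively and the query is de-duplicated on
#' entry. The universe defaults to the union of all collection genes;
#' supplying the array's full gene list instead materially changes p-values
#' and is recommended when available.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param mode `"fisher"` (default) or `"ease"`.
#' @param universe Optional background symbol vector; defaults to the union
#'   of all sets. Sets and query are restricted to it.
#' @return Data.frame: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `pvalue`, `fdr`, ordered as in the collection.
#' @export
enrich <- function(query, collection, mode = c("fisher", "ease"),
                   universe = NULL) {
  mode <- match.arg(mode)
  if (length(query) == 0L) stop("query is empty")
  if (length(collection) == 0L) stop("collection is empty")
  norm <- function(x) unique(toupper(as.character(x)))
  sets <- lapply(collection, norm)
  uni <- if (is.null(universe)) unique(unlist(sets)) else norm(universe)
  if (length(uni) == 0L) stop("universe is empty")
  sets <- lapply(sets, intersect, uni)
  q <- intersect(norm(query), uni)
  if (length(q) == 0L) stop("no query genes found in the universe")
  N <- length(uni)
  n_q <- length(q)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    k <- length(intersect(q, s))
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    # upper tail: P(overlap >= k_eff) drawing n_q from N with length(s) marked
    p <- if (k_eff == 0L) 1
         else stats::phyper(k_eff - 1L, length(s), N - length(s), n_q,
                            lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = n_q, universe_size = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$pvalue)
  tab
}
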