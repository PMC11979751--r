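#' Gene set collection
#'
#' Named, non-empty gene sets, as read from a GMT file.
#'
#' @param sets Named list of character vectors.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0 || is.null(names(sets)))
    stop("'sets' must be a non-empty named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name: ",
         names(sets)[which(duplicated(names(sets)))[1]])
  if (any(lengths(sets) == 0))
    stop("empty gene set: ", names(sets)[which(lengths(sets) == 0)[1]])
  structure(list(sets = lapply(sets, as.character)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %d..%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Fisher exact enrichment of a query gene list
#'
#' One-sided Fisher exact test of the query against every set, on the 2x2
#' table (query-and-set, query-not-set, set-not-query, neither) over the
#' given universe. Sets are intersected with the universe first. P-values
#' are Benjamini-Hochberg adjusted across sets; the odds ratio reported is
#' the sample (cross-product) estimate, 0 when the overlap is empty.
#'
#' @param query Character vector of genes (must lie in `universe`).
#' @param collection A [gene_set_collection()] or named list of gene sets.
#' @param universe Character vector of all genes under consideration.
#' @param alpha Adjusted-p significance cutoff reported in `significant`.
#' @return Data frame `set`, `set_size`, `overlap`, `odds_ratio`, `p`,
#'   `p_adj`, `significant`, ordered by increasing p.
#' @export
fisher_enrichment <- function(query, collection, universe, alpha = 0.05) {
  if (!inherits(collection, "gene_set_collection"))
    collection <- gene_set_collection(collection)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0) stop("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene not in universe: ", outside[1])
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    a <- length(intersect(query, s))
    b <- n_q - a
    cc <- length(s) - a
    d <- n_u - n_q - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    if (a == 0) or <- 0
    data.frame(set = nm, set_size = length(s), overlap = a,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
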