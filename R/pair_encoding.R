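#' Intersect single-cell and bulk gene universes
#'
#' Returns the genes measured in both datasets, sorted lexicographically so
#' the result is deterministic regardless of input order.
#'
#' @param sc_genes,bulk_genes Character vectors of gene identifiers.
#' @return Sorted character vector of shared genes.
#' @export
intersect_genes <- function(sc_genes, bulk_genes) {
  if (length(sc_genes) == 0 || length(bulk_genes) == 0)
    stop("gene lists must be non-empty")
  shared <- sort(intersect(sc_genes, bulk_genes), method = "radix")
  if (length(shared) == 0)
    stop("no genes shared between the two datasets: incompatible gene universes")
  shared
}

#' Select the most variable genes by median absolute deviation
#'
#' Scores each shared gene by the median over cells of the absolute
#' deviation from its own median (MAD without the consistency constant) and
#' keeps the `n_top` highest-scoring genes. Ties are broken by gene name so
#' the selection is deterministic.
#'
#' @param sc_matrix Single-cell [expression_matrix()] or genes x cells matrix.
#' @param shared Character vector of genes to score (must be in the matrix).
#' @param n_top Number of genes to retain (default 3000).
#' @return Character vector of selected genes (ordered by gene position in
#'   `shared`), with the per-gene scores attached as the `scores` attribute
#'   (named, for all of `shared`).
#' @export
select_variable_genes <- function(sc_matrix, shared, n_top = 3000) {
  x <- em_values(sc_matrix)
  missing <- setdiff(shared, rownames(x))
  if (length(missing))
    stop("genes absent from single-cell matrix: ", missing[1])
  x <- x[shared, , drop = FALSE]
  med <- apply(x, 1, stats::median)
  scores <- apply(abs(x - med), 1, stats::median)
  names(scores) <- shared
  k <- min(n_top, length(shared))
  ord <- order(scores, shared, decreasing = TRUE)   # score desc, name desc tiebreak
  keep <- sort(ord[seq_len(k)])
  sel <- shared[keep]
  attr(sel, "scores") <- scores
  sel
}

#' Enumerate canonical gene pairs
#'
#' All unordered pairs of distinct genes from `selected`, each emitted once
#' with the gene that appears earlier in `selected` first. The first/second
#' positions are therefore well defined for the strict-inequality encoding.
#'
#' @param selected Character vector of genes (>= 2).
#' @return Two-column character matrix (`first`, `second`).
#' @export
enumerate_pairs <- function(selected) {
  n <- length(selected)
  if (n < 2) stop("need at least 2 genes to form pairs")
  if (anyDuplicated(selected)) stop("duplicate genes in 'selected'")
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n), use.names = FALSE)
  cbind(first = selected[i], second = selected[j])
}

# Map pair gene names to row indices of a matrix, with a located error.
pair_indices <- function(pairs, x) {
  idx1 <- match(pairs[, 1], rownames(x))
  idx2 <- match(pairs[, 2], rownames(x))
  bad <- c(pairs[, 1][is.na(idx1)], pairs[, 2][is.na(idx2)])
  if (length(bad)) stop("gene missing from matrix: ", bad[1])
  cbind(idx1, idx2)
}

#' Bulk concordance of gene pairs
#'
#' For each pair, the fraction of bulk samples in which the first gene's
#' expression strictly exceeds the second's. Ties contribute 0. Computed in
#' chunks over pairs so memory stays bounded for large pair lists; results
#' are identical to the dense computation.
#'
#' @param bulk Bulk [expression_matrix()] or genes x samples matrix.
#' @param pairs Two-column character matrix from [enumerate_pairs()].
#' @param chunk_size Pairs processed per chunk.
#' @return Numeric vector of per-pair concordances in \[0, 1\].
#' @export
bulk_concordance <- function(bulk, pairs, chunk_size = 100000L) {
  x <- em_values(bulk)
  if (ncol(x) < 1) stop("bulk matrix must have at least one sample")
  idx <- pair_indices(pairs, x)
  n_pairs <- nrow(idx)
  out <- numeric(n_pairs)
  start <- 1L
  while (start <= n_pairs) {
    end <- min(start + chunk_size - 1L, n_pairs)
    sl <- start:end
    # samples x chunk comparison, column means = concordance
    a <- t(x[idx[sl, 1], , drop = FALSE])
    b <- t(x[idx[sl, 2], , drop = FALSE])
    out[sl] <- colMeans(a > b)
    start <- end + 1L
  }
  out
}

#' Filter gene pairs by bulk concordance
#'
#' Retains pairs whose concordance lies in `[lo, hi]`, both ends inclusive.
#' Pairs near 0.5 are maximally discriminative across bulk samples.
#'
#' @param pairs Two-column character matrix.
#' @param concordance Per-pair concordance aligned with `pairs`.
#' @param lo,hi Inclusive bounds (defaults 0.49 and 0.51).
#' @return The retained rows of `pairs`, with retained concordances attached
#'   as the `concordance` attribute.
#' @export
filter_pairs <- function(pairs, concordance, lo = 0.49, hi = 0.51) {
  if (lo > hi) stop("lo must be <= hi")
  if (nrow(pairs) != length(concordance))
    stop("pairs and concordance are not aligned")
  keep <- concordance >= lo & concordance <= hi
  out <- pairs[keep, , drop = FALSE]
  attr(out, "concordance") <- concordance[keep]
  out
}

#' Binary relative-expression encoding
#'
#' Encodes each observation as a binary vector over gene pairs: entry 1 iff
#' the first gene's expression strictly exceeds the second's within that
#' observation, else 0 (ties are 0). Because each feature only compares two
#' genes within the same observation, the encoding is invariant to any
#' strictly monotone within-observation transform, which removes
#' batch/patient-level distortions. Applies identically to single-cell and
#' bulk matrices.
#'
#' @param matrix An [expression_matrix()] or genes x observations matrix.
#' @param pairs Two-column character matrix of gene pairs.
#' @param source_id Optional dataset tag stored on the result.
#' @return A `binary_relative` object: list with `values` (observations x
#'   pairs 0/1 matrix), `pairs`, and `source_id`.
#' @export
encode_relative <- function(matrix, pairs, source_id = NULL) {
  x <- em_values(matrix)
  idx <- pair_indices(pairs, x)
  v <- t((x[idx[, 1], , drop = FALSE] > x[idx[, 2], , drop = FALSE]) * 1L)
  dimnames(v) <- list(colnames(x), paste(pairs[, 1], pairs[, 2], sep = "|"))
  structure(list(values = v, pairs = pairs, source_id = source_id),
            class = "binary_relative")
}

#' @export
print.binary_relative <- function(x, ...) {
  cat(sprintf("<binary_relative> %d observations x %d pairs%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

#' Build the full relative-expression encoding
#'
#' Convenience composition of the encoding pipeline: intersect gene
#' universes, select the `n_top` most variable genes in the single-cell
#' data, enumerate canonical pairs, compute bulk concordance, and filter
#' pairs to the `[lo, hi]` concordance band.
#'
#' @param sc Single-cell [expression_matrix()].
#' @param bulk Bulk [expression_matrix()].
#' @inheritParams select_variable_genes
#' @inheritParams filter_pairs
#' @param chunk_size Pairs per concordance chunk.
#' @return A `relative_encoding` object: list with `shared_genes`,
#'   `selected_genes` (with MAD scores), `pairs` (retained, P2),
#'   `concordance` (retained), `n_pairs_enumerated`, `n_top`, and `bounds`.
#' @export
relative_encoding <- function(sc, bulk, n_top = 3000, lo = 0.49, hi = 0.51,
                              chunk_size = 100000L) {
  shared <- intersect_genes(rownames(em_values(sc)), rownames(em_values(bulk)))
  selected <- select_variable_genes(sc, shared, n_top = n_top)
  p1 <- enumerate_pairs(as.character(selected))
  conc <- bulk_concordance(bulk, p1, chunk_size = chunk_size)
  p2 <- filter_pairs(p1, conc, lo = lo, hi = hi)
  structure(list(shared_genes = shared,
                 selected_genes = selected,
                 pairs = p2[, , drop = FALSE],
                 concordance = attr(p2, "concordance"),
                 n_pairs_enumerated = nrow(p1),
                 n_top = n_top, bounds = c(lo = lo, hi = hi)),
            class = "relative_encoding")
}

#' @export
print.relative_encoding <- function(x, ...) {
  cat(sprintf(paste0("<relative_encoding> %d shared genes, %d selected, ",
                     "%d/%d pairs in [%.3g, %.3g]\n"),
              length(x$shared_genes), length(x$selected_genes),
              nrow(x$pairs), x$n_pairs_enumerated,
              x$bounds["lo"], x$bounds["hi"]))
  invisible(x)
}
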