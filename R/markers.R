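#' Per-state detection fractions
#'
#' Fraction of cells in each state with expression strictly greater than
#' zero, per gene.
#'
#' @param matrix [expression_matrix()] or genes x cells matrix.
#' @param labels Per-cell state labels.
#' @return Genes x states matrix of fractions in \[0, 1\].
#' @export
detection_fractions <- function(matrix, labels) {
  x <- em_values(matrix)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x))
    stop("labels length does not match number of cells")
  if (any(table(labels) == 0))
    stop("empty state: ", names(which(table(labels) == 0))[1])
  det <- vapply(levels(labels),
                function(s) rowMeans(x[, labels == s, drop = FALSE] > 0),
                numeric(nrow(x)))
  dimnames(det) <- list(rownames(x), levels(labels))
  det
}

#' Specificity distance of a detection vector to a state
#'
#' One minus the cosine similarity between a gene's per-state detection
#' fraction vector and the one-hot indicator of the target state: 0 means
#' the gene is detected only in the target state (perfect specificity),
#' 1 means it is never detected there. An all-zero detection vector (gene
#' undetected everywhere) is defined as maximally non-specific, sd = 1, and
#' flagged via the `undetected` attribute.
#'
#' @param detection_row Numeric vector of per-state detection fractions.
#' @param state Index (or name, if `detection_row` is named) of the target
#'   state.
#' @return Numeric scalar in \[0, 1\] with attribute `undetected`.
#' @export
specificity_distance <- function(detection_row, state) {
  u <- as.numeric(detection_row)
  if (any(u < 0) || any(u > 1)) stop("detection fractions must be in [0, 1]")
  if (is.character(state)) state <- match(state, names(detection_row))
  if (is.na(state) || state < 1 || state > length(u))
    stop("invalid state index")
  nu <- sqrt(sum(u^2))
  if (nu == 0)
    return(structure(1, undetected = TRUE))
  sd_ <- 1 - u[state] / nu
  structure(min(max(sd_, 0), 1), undetected = FALSE)
}

# Vectorised specificity distance for a detection matrix: genes x states in,
# genes x states out.
specificity_distance_matrix <- function(detection) {
  nu <- sqrt(rowSums(detection^2))
  sd_ <- 1 - sweep(detection, 1, pmax(nu, .Machine$double.xmin), "/")
  sd_[nu == 0, ] <- 1
  sd_ <- pmin(pmax(sd_, 0), 1)
  attr(sd_, "undetected") <- nu == 0
  sd_
}

#' Select markers for one state from specificity and fold-change scores
#'
#' Groups the per-gene specificity distances into `n_groups` by exact 1-D
#' k-means, takes the group with the lowest mean specificity distance as the
#' candidate set, and returns up to `top_n` candidates ranked by descending
#' fold-change.
#'
#' @param sd_values Named numeric vector of per-gene specificity distances
#'   for the state.
#' @param fold_change Named numeric vector of per-gene fold-changes, aligned
#'   with `sd_values`.
#' @param top_n Maximum number of markers (default 80).
#' @param n_groups Number of k-means groups (default 10).
#' @return Data frame `gene`, `fold_change`, `sd`, ordered by descending
#'   fold-change.
#' @export
select_state_markers <- function(sd_values, fold_change, top_n = 80,
                                 n_groups = 10) {
  if (length(sd_values) < n_groups)
    stop("fewer genes (", length(sd_values), ") than n_groups (", n_groups, ")")
  if (length(fold_change) != length(sd_values))
    stop("sd_values and fold_change are not aligned")
  km <- kmeans_1d(as.numeric(sd_values), n_groups)
  best <- which.min(km$centers)   # centres are group means; lowest wins
  cand <- which(km$cluster == best)
  ord <- cand[order(-fold_change[cand], names(sd_values)[cand])]
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene = names(sd_values)[keep],
             fold_change = unname(fold_change[keep]),
             sd = unname(sd_values[keep]),
             stringsAsFactors = FALSE)
}

#' Select state-specific marker genes
#'
#' For every state: computes per-gene specificity distances from the
#' detection fractions, groups them with exact 1-D k-means into `n_groups`,
#' keeps the group with the lowest mean specificity distance, and returns up
#' to `top_n` of those candidates with the highest fold-change. Fold-change
#' is computed on linear TPM values, `(mean in state + eps) / (mean in rest
#' + eps)`.
#'
#' @param matrix [expression_matrix()] or genes x cells matrix (logTPM
#'   assumed for bare matrices).
#' @param labels Per-cell state labels.
#' @param top_n Markers per state (default 80).
#' @param n_groups k-means groups on the specificity distances (default 10).
#' @param seed Accepted for interface stability; the exact dynamic-programming
#'   k-means makes the selection deterministic, so the seed is unused.
#' @param eps Pseudo-expression for the fold-change ratio.
#' @return A `marker_set`: list with `markers` (per-state data frames of
#'   `gene`, `fold_change`, `sd`), `detection`, `sd` (genes x states), and
#'   the selection parameters.
#' @export
select_markers <- function(matrix, labels, top_n = 80, n_groups = 10,
                           seed = 1, eps = 1e-9) {
  labels <- as.factor(labels)
  det <- detection_fractions(matrix, labels)
  sd_mat <- specificity_distance_matrix(det)
  tpm <- em_as_space(matrix, "TPM")
  if (nrow(tpm) < n_groups)
    stop("fewer genes (", nrow(tpm), ") than n_groups (", n_groups, ")")
  states <- levels(labels)
  markers <- list()
  for (s in states) {
    in_state <- labels == s
    fc <- (rowMeans(tpm[, in_state, drop = FALSE]) + eps) /
      (rowMeans(tpm[, !in_state, drop = FALSE]) + eps)
    sdv <- sd_mat[, s]
    names(sdv) <- rownames(tpm)
    markers[[s]] <- select_state_markers(sdv, fc, top_n = top_n,
                                         n_groups = n_groups)
  }
  structure(list(markers = markers, detection = det, sd = sd_mat,
                 top_n = top_n, n_groups = n_groups),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s\n",
              paste(sprintf("%s: %d", names(x$markers),
                            vapply(x$markers, nrow, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' All marker genes of a marker set
#'
#' @param markers A `marker_set`.
#' @return Character vector, union over states, in state order.
#' @export
marker_genes <- function(markers) {
  unique(unlist(lapply(markers$markers, `[[`, "gene"), use.names = FALSE))
}

#' Select genes by discordance score
#'
#' Multiplies each significantly upregulated gene's repressive tendency
#' score (an external per-gene input) by its rank-sum location parameter and
#' returns the `top_n` genes with the highest product. Genes without a
#' repressive tendency score are excluded.
#'
#' @param de_table One state's rows of a [de_one_vs_rest()] result.
#' @param rts Named numeric vector of repressive tendency scores.
#' @param top_n Number of genes to return (default 500).
#' @param alpha Adjusted-p cutoff defining the upregulated set.
#' @return Data frame `gene`, `score`, `rts`, `location`, ordered by
#'   descending score.
#' @export
discordance_select <- function(de_table, rts, top_n = 500, alpha = 0.05) {
  up <- de_table[de_table$direction > 0 & de_table$p_adj < alpha, ]
  if (nrow(up) == 0) {
    warning("no upregulated genes; returning empty selection")
    return(data.frame(gene = character(0), score = numeric(0),
                      rts = numeric(0), location = numeric(0)))
  }
  r <- rts[up$gene]
  keep <- !is.na(r)
  up <- up[keep, ]; r <- r[keep]
  score <- r * up$location
  ord <- order(-score, up$gene)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene = up$gene[keep], score = unname(score[keep]),
             rts = unname(r[keep]), location = up$location[keep],
             stringsAsFactors = FALSE)
}
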