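#' Cluster cells on the binary relative-expression matrix
#'
#' Complete-linkage hierarchical clustering with Euclidean distance on the
#' observations of a binary relative matrix, cut into `n_clusters` states.
#' Deterministic for fixed input.
#'
#' @param binary A `binary_relative` object or observations x features matrix.
#' @param n_clusters Number of states to cut the dendrogram into.
#' @return Factor of state labels (`state1`, `state2`, ...) named by
#'   observation, ordered by cluster appearance in the input.
#' @export
cluster_cells <- function(binary, n_clusters) {
  v <- if (inherits(binary, "binary_relative")) binary$values else binary
  if (n_clusters > nrow(v))
    stop("n_clusters exceeds the number of observations")
  hc <- stats::hclust(stats::dist(v, method = "euclidean"),
                      method = "complete")
  cut <- stats::cutree(hc, k = n_clusters)
  # relabel in order of first appearance so labels are input-order stable
  first <- order(match(unique(cut[order(seq_along(cut))]), cut))
  lab <- factor(cut, levels = unique(cut))
  levels(lab) <- paste0("state", seq_along(levels(lab)))
  names(lab) <- rownames(v)
  lab
}

#' Fit the PCA trajectory model
#'
#' Mean-centred PCA of the binary relative-expression matrix. The component
#' weights and the training means define the trajectory space into which
#' external datasets encoded on the same pairs can be projected.
#'
#' @param binary A `binary_relative` object or observations x pairs matrix.
#' @param n_components Number of components to keep.
#' @param cluster_labels Optional per-observation state labels stored on the
#'   model.
#' @return A `trajectory_model`: list with `components` (components x pairs),
#'   `training_means`, `explained_variance`, `explained_variance_ratio`,
#'   `coordinates` (training observations x components), `pairs`,
#'   `cluster_labels`.
#' @export
fit_pca <- function(binary, n_components = 2, cluster_labels = NULL) {
  v <- if (inherits(binary, "binary_relative")) binary$values else binary
  pairs <- if (inherits(binary, "binary_relative")) binary$pairs else NULL
  if (n_components > min(dim(v)))
    stop("n_components exceeds min(observations, pairs)")
  vars <- apply(v, 2, stats::var)
  if (all(vars < .Machine$double.eps))
    stop("binary matrix has zero variance in every column; PCA is degenerate")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- pc$sdev^2
  structure(list(components = t(pc$rotation),          # comp x pairs
                 training_means = pc$center,
                 explained_variance = ev[seq_len(n_components)],
                 explained_variance_ratio =
                   ev[seq_len(n_components)] / sum(ev),
                 coordinates = pc$x,
                 pairs = pairs,
                 cluster_labels = cluster_labels),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> %d components over %d pairs (evr %s)\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.3f", x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Project a binary matrix into a fitted trajectory space
#'
#' Centres the encoded observations with the training means and takes the
#' dot product with the stored component weights. Any dataset encoded on the
#' same gene pairs (bulk or single-cell) can be projected.
#'
#' @param model A `trajectory_model` from [fit_pca()].
#' @param binary A `binary_relative` object built on the same pair list.
#' @return Observations x components coordinate matrix.
#' @export
project_trajectory <- function(model, binary) {
  v <- if (inherits(binary, "binary_relative")) binary$values else binary
  bp <- if (inherits(binary, "binary_relative")) binary$pairs else NULL
  if (!is.null(model$pairs) && !is.null(bp)) {
    if (nrow(model$pairs) != nrow(bp))
      stop("pair-list mismatch: model has ", nrow(model$pairs),
           " pairs, input has ", nrow(bp))
    diff <- which(model$pairs[, 1] != bp[, 1] | model$pairs[, 2] != bp[, 2])
    if (length(diff))
      stop("pair-list mismatch at pair ", diff[1], ": model (",
           paste(model$pairs[diff[1], ], collapse = ","), ") vs input (",
           paste(bp[diff[1], ], collapse = ","), ")")
  }
  if (ncol(v) != length(model$training_means))
    stop("input has ", ncol(v), " features but model was trained on ",
         length(model$training_means))
  sweep(v, 2, model$training_means) %*% t(model$components)
}

# Hodges-Lehmann shift estimate: median of all pairwise differences.
hl_shift <- function(x, y) stats::median(outer(x, y, "-"))

#' One-versus-rest differential expression
#'
#' For every gene and every state, tests the state's observations against
#' all remaining observations with a Wilcoxon rank-sum test (exact when both
#' groups have <= 25 observations and no ties, normal approximation with
#' continuity and tie correction otherwise) or Welch t-test. P-values are
#' Bonferroni-corrected over the full genes x states family. The location
#' shift is the Hodges-Lehmann estimate (median of pairwise differences) for
#' the rank-sum test and the difference in means for the t-test.
#'
#' @param matrix [expression_matrix()] or genes x observations matrix.
#' @param labels Per-observation state labels.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @return Data frame with columns `gene`, `state`, `statistic`, `p`,
#'   `p_adj`, `location`, `direction`, `significant` (p_adj < 0.05).
#' @export
de_one_vs_rest <- function(matrix, labels, test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  x <- em_values(matrix)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x))
    stop("labels length does not match number of observations")
  if (nlevels(labels) < 2) stop("need at least 2 states")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("state with fewer than 2 observations: ",
         names(sizes)[which(sizes < 2)[1]])
  states <- levels(labels)
  n_tests <- nrow(x) * length(states)
  res <- vector("list", length(states))
  for (si in seq_along(states)) {
    in_state <- labels == states[si]
    stat <- p <- loc <- numeric(nrow(x))
    for (g in seq_len(nrow(x))) {
      a <- x[g, in_state]; b <- x[g, !in_state]
      if (test == "wilcoxon") {
        ht <- suppressWarnings(stats::wilcox.test(
          a, b, alternative = "two.sided",
          exact = (length(a) <= 25 && length(b) <= 25), correct = TRUE))
        stat[g] <- unname(ht$statistic)
        p[g] <- ht$p.value
        loc[g] <- hl_shift(a, b)
      } else {
        loc[g] <- mean(a) - mean(b)
        ht <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
        if (is.null(ht)) {     # essentially constant data
          stat[g] <- 0
          p[g] <- as.numeric(isTRUE(all.equal(mean(a), mean(b))))
        } else {
          stat[g] <- unname(ht$statistic); p[g] <- ht$p.value
        }
      }
      if (is.na(p[g])) p[g] <- 1   # constant gene: no evidence
    }
    res[[si]] <- data.frame(gene = rownames(x), state = states[si],
                            statistic = stat, p = p,
                            p_adj = pmin(1, p * n_tests),
                            location = loc,
                            direction = sign(loc),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Spearman correlation of genes with a principal component
#'
#' Correlates every gene's expression across observations with the chosen
#' PC coordinate (Spearman), Bonferroni-corrects over genes, and returns the
#' significantly correlated genes ranked from most positive to most negative
#' rho — the ranked-list input for preranked GSEA tools.
#'
#' @param matrix [expression_matrix()] or genes x observations matrix.
#' @param coordinates Observations x components coordinate matrix (or a
#'   vector of per-observation PC values).
#' @param component Column of `coordinates` to use.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return Data frame `gene`, `rho`, `p`, `p_adj`, significant genes only,
#'   ordered by decreasing rho. The full unfiltered table is attached as the
#'   `full` attribute.
#' @export
pc_gene_correlation <- function(matrix, coordinates, component = 1,
                                alpha = 0.05) {
  x <- em_values(matrix)
  pc <- if (is.matrix(coordinates)) coordinates[, component] else coordinates
  if (length(pc) != ncol(x))
    stop("coordinates do not align with observations")
  if (stats::sd(pc) == 0) stop("PC vector is constant; correlation undefined")
  rho <- p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    if (stats::sd(x[g, ]) == 0) { rho[g] <- 0; p[g] <- 1; next }
    ht <- suppressWarnings(stats::cor.test(x[g, ], pc, method = "spearman"))
    rho[g] <- unname(ht$estimate); p[g] <- ht$p.value
  }
  full <- data.frame(gene = rownames(x), rho = rho, p = p,
                     p_adj = pmin(1, p * nrow(x)), stringsAsFactors = FALSE)
  full <- full[order(-full$rho, full$gene), ]
  rownames(full) <- NULL
  out <- full[full$p_adj < alpha, ]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Cross-tabulate state labels against joint-cluster labels
#'
#' For each state, the fraction of its cells falling in each joint cluster.
#' Rows (states) sum to 1. Used to match states across studies after a
#' joint clustering.
#'
#' @param labels_a Per-cell state labels.
#' @param labels_joint Per-cell joint-cluster labels.
#' @return States x joint-clusters proportion matrix.
#' @export
crosstab_state_proportions <- function(labels_a, labels_joint) {
  if (length(labels_a) != length(labels_joint))
    stop("label vectors have different lengths")
  tab <- table(labels_a, labels_joint)
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}
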