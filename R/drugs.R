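#' Drug signature set
#'
#' Container for per-drug up/down differential-expression gene lists over a
#' common gene universe, with optional mechanism-of-action labels and target
#' genes.
#'
#' @param drugs Named list; each element a list with character vectors `up`
#'   and `down` (disjoint).
#' @param universe Character vector of all genes signatures may mention.
#' @param moa Optional named character vector of mechanism labels per drug.
#' @param targets Optional named list of target genes per drug.
#' @return A `drug_signature_set`.
#' @export
drug_signature_set <- function(drugs, universe, moa = NULL, targets = NULL) {
  if (length(drugs) == 0 || is.null(names(drugs)))
    stop("'drugs' must be a non-empty named list")
  universe <- as.character(universe)
  for (d in names(drugs)) {
    sig <- drugs[[d]]
    both <- intersect(sig$up, sig$down)
    if (length(both))
      stop("drug '", d, "': gene '", both[1],
           "' in both up and down sets")
    out <- setdiff(c(sig$up, sig$down), universe)
    if (length(out))
      stop("drug '", d, "': gene '", out[1], "' not in universe")
  }
  structure(list(drugs = drugs, universe = universe, moa = moa,
                 targets = targets),
            class = "drug_signature_set")
}

#' @export
print.drug_signature_set <- function(x, ...) {
  cat(sprintf("<drug_signature_set> %d drugs over %d genes%s\n",
              length(x$drugs), length(x$universe),
              if (is.null(x$moa)) "" else
                sprintf(" (%d MOA classes)", length(unique(x$moa)))))
  invisible(x)
}

#' Signed drug-signature matrix
#'
#' Drugs x genes matrix with entry 1 for genes up-regulated by the drug,
#' -1 for down-regulated, 0 otherwise.
#'
#' @param signatures A [drug_signature_set()].
#' @return Integer matrix over \{-1, 0, 1\}, drugs as rows, the universe as
#'   columns.
#' @export
build_sign_matrix <- function(signatures) {
  if (!inherits(signatures, "drug_signature_set"))
    stop("expected a drug_signature_set")
  u <- signatures$universe
  D <- matrix(0L, length(signatures$drugs), length(u),
              dimnames = list(names(signatures$drugs), u))
  for (d in names(signatures$drugs)) {
    D[d, signatures$drugs[[d]]$up] <- 1L
    D[d, signatures$drugs[[d]]$down] <- -1L
  }
  D
}

# All-pairs normalized hamming distances over the 3-symbol alphabet: the
# fraction of gene positions with unequal entries.
hamming_matrix <- function(D) {
  n <- nrow(D)
  out <- matrix(0, n, n, dimnames = list(rownames(D), rownames(D)))
  for (i in seq_len(n)) {
    diffs <- sweep(D, 2, D[i, ], "!=")
    out[i, ] <- rowMeans(diffs)
  }
  (out + t(out)) / 2   # enforce exact symmetry against fp noise
}

# UMAP-style fuzzy connectivity weights for a kNN graph: local scaling with
# smooth-kNN calibration, then probabilistic union symmetrization. Mirrors
# the neighbour-weighting used by the standard single-cell toolkits.
knn_connectivities <- function(dist_mat, k) {
  n <- nrow(dist_mat)
  W <- matrix(0, n, n, dimnames = dimnames(dist_mat))
  target <- log2(k)
  for (i in seq_len(n)) {
    d <- dist_mat[i, -i]
    nb <- order(d)[seq_len(k)]
    dn <- d[nb]
    rho <- min(dn)   # includes zero distances so duplicates stay maximal
    adj <- pmax(dn - rho, 0)
    lo <- 1e-6; hi <- max(adj) + 1
    if (all(adj == 0)) sigma <- 1 else {
      for (it in 1:64) {
        sigma <- (lo + hi) / 2
        s <- sum(exp(-adj / sigma))
        if (s > target) hi <- sigma else lo <- sigma
      }
    }
    idx <- setdiff(seq_len(n), i)[nb]
    W[i, idx] <- exp(-adj / sigma)
  }
  W + t(W) - W * t(W)
}

#' Drug similarity graph under hamming distance
#'
#' Builds a k-nearest-neighbour graph over drugs using the normalised
#' hamming distance between signed signature rows (any symbol mismatch
#' counts once), symmetrised by union, with UMAP-style fuzzy connectivity
#' edge weights.
#'
#' @param D Signed drugs x genes matrix from [build_sign_matrix()].
#' @param k Number of nearest neighbours (default 15).
#' @return A `drug_graph`: list with `graph` (igraph, weighted), `distances`
#'   (all-pairs hamming), `connectivities`, `k`, and empty `clusters` /
#'   `embedding` slots filled by [cluster_drugs()] / [embed_drugs()].
#' @export
drug_similarity_graph <- function(D, k = 15) {
  n <- nrow(D)
  if (k >= n) stop("k (", k, ") must be smaller than the number of drugs (",
                   n, ")")
  dm <- hamming_matrix(D)
  W <- knn_connectivities(dm, k)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  structure(list(graph = g, distances = dm, connectivities = W, k = k,
                 clusters = NULL, embedding = NULL, params = list(k = k)),
            class = "drug_graph")
}

#' @export
print.drug_graph <- function(x, ...) {
  cat(sprintf("<drug_graph> %d drugs, k=%d%s\n",
              nrow(x$distances), x$k,
              if (is.null(x$clusters)) "" else
                sprintf(", %d clusters", length(unique(x$clusters)))))
  invisible(x)
}

#' Leiden clustering of the drug graph
#'
#' Community detection on the weighted neighbour graph with the Leiden
#' algorithm (modularity objective) at the given resolution. The seed is set
#' before clustering so labels are reproducible.
#'
#' @param graph A `drug_graph`.
#' @param resolution Leiden resolution parameter (default 2.95).
#' @param seed Integer RNG seed.
#' @return The `drug_graph` with `clusters` (named integer labels) and
#'   recorded parameters.
#' @export
cluster_drugs <- function(graph, resolution = 2.95, seed = 1) {
  if (!inherits(graph, "drug_graph")) stop("expected a drug_graph")
  if (igraph::vcount(graph$graph) == 0) stop("empty drug graph")
  set.seed(seed)
  comm <- igraph::cluster_leiden(graph$graph,
                                 objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 10)
  labels <- igraph::membership(comm)
  graph$clusters <- stats::setNames(as.integer(labels),
                                    igraph::V(graph$graph)$name)
  graph$params$resolution <- resolution
  graph$params$cluster_seed <- seed
  graph
}

#' 2-D UMAP embedding of the drug graph
#'
#' Embeds drugs with UMAP on the precomputed hamming distances. Decorative:
#' only seed-determinism and coarse class separation are meaningful, never
#' exact coordinates.
#'
#' @param graph A `drug_graph`.
#' @param seed Integer RNG seed.
#' @return The `drug_graph` with `embedding` (drugs x 2 coordinates).
#' @export
embed_drugs <- function(graph, seed = 1) {
  if (!inherits(graph, "drug_graph")) stop("expected a drug_graph")
  n <- nrow(graph$distances)
  set.seed(seed)
  coords <- uwot::umap(stats::as.dist(graph$distances),
                       n_neighbors = min(graph$k, n - 1),
                       init = "spectral", n_threads = 1, n_sgd_threads = 0)
  rownames(coords) <- rownames(graph$distances)
  colnames(coords) <- c("UMAP1", "UMAP2")
  graph$embedding <- coords
  graph$params$embed_seed <- seed
  graph
}

#' Sensitivity table with target flags
#'
#' Wraps a drug x (study, state) susceptibility score matrix (for example
#' BeyondCell residual means) and binarises it into "predicted to target"
#' flags. The default rule flags the `top_n` drugs per column by score; the
#' rule is recorded with the table.
#'
#' @param scores Numeric matrix, drugs as rows, (study, state) combinations
#'   as columns; higher = more susceptible.
#' @param top_n Drugs flagged per column (default 10).
#' @return A `sensitivity_table`: list with `scores`, `flags` (logical
#'   matrix), and `rule`.
#' @export
sensitivity_table <- function(scores, top_n = 10) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("drug", seq_len(nrow(scores)))
  if (top_n < 1 || top_n > nrow(scores))
    stop("top_n must be between 1 and the number of drugs")
  flags <- apply(scores, 2, function(col) {
    cutoff <- sort(col, decreasing = TRUE)[top_n]
    sel <- col >= cutoff
    if (sum(sel) > top_n) {  # break score ties by drug identifier
      tied <- names(col)[sel & col == cutoff]
      drop_n <- sum(sel) - top_n
      sel[utils::tail(sort(tied), drop_n)] <- FALSE
    }
    sel
  })
  rownames(flags) <- rownames(scores)
  structure(list(scores = scores, flags = flags,
                 rule = sprintf("top %d drugs per (study,state) by score",
                                top_n)),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("<sensitivity_table> %d drugs x %d (study,state) columns; %s\n",
              nrow(x$scores), ncol(x$scores), x$rule))
  invisible(x)
}

#' Drug-susceptibility overlap between states
#'
#' Symmetric matrix counting, for every pair of (study, state) columns, the
#' drugs predicted to target both; the diagonal counts each column's own
#' targeted drugs.
#'
#' @param sens A [sensitivity_table()].
#' @return Integer (study,state) x (study,state) matrix.
#' @export
overlap_matrix <- function(sens) {
  if (!inherits(sens, "sensitivity_table")) stop("expected a sensitivity_table")
  f <- sens$flags * 1L
  out <- t(f) %*% f
  storage.mode(out) <- "integer"
  out
}

#' Rank drugs by number of targeted states
#'
#' Counts, per drug, the number of (study, state) columns it is flagged to
#' target, returned in descending order with ties broken by drug identifier.
#'
#' @param sens A [sensitivity_table()].
#' @return Data frame `drug`, `n_states`.
#' @export
rank_drugs_by_states <- function(sens) {
  if (!inherits(sens, "sensitivity_table")) stop("expected a sensitivity_table")
  counts <- rowSums(sens$flags)
  ord <- order(-counts, names(counts))
  data.frame(drug = names(counts)[ord], n_states = unname(counts[ord]),
             stringsAsFactors = FALSE)
}

#' Summarise drug-target gene expression across datasets
#'
#' For each target gene, dataset and state: mean expression and detection
#' fraction, plus a cross-dataset consistency flag — whether the gene is
#' detected (fraction above `threshold`) in the invasive-labelled state of
#' every dataset. Genes absent from a dataset get NA rows and are flagged
#' inconsistent.
#'
#' @param datasets Named list; each element a list with `matrix`
#'   ([expression_matrix()] or genes x cells matrix), `labels`
#'   (per-cell states), and `invasive_state` (the state label regarded as
#'   invasive in that dataset).
#' @param target_genes Named list of gene vectors (for example per drug
#'   cluster), or a single character vector.
#' @param threshold Detection-fraction threshold (default 0.1).
#' @return List with `summary` (long data frame: `gene`, `group`, `dataset`,
#'   `state`, `mean_expr`, `detection`) and `consistency` (per gene:
#'   `consistent` logical).
#' @export
target_expression_summary <- function(datasets, target_genes,
                                      threshold = 0.1) {
  if (!is.list(target_genes) || is.null(names(target_genes)))
    target_genes <- list(targets = as.character(unlist(target_genes)))
  rows <- list()
  genes_all <- unique(unlist(target_genes, use.names = FALSE))
  inv_det <- matrix(NA_real_, length(genes_all), length(datasets),
                    dimnames = list(genes_all, names(datasets)))
  for (ds in names(datasets)) {
    x <- em_values(datasets[[ds]]$matrix)
    labels <- as.factor(datasets[[ds]]$labels)
    inv <- datasets[[ds]]$invasive_state
    for (grp in names(target_genes)) {
      for (gene in target_genes[[grp]]) {
        present <- gene %in% rownames(x)
        for (s in levels(labels)) {
          cells <- labels == s
          rows[[length(rows) + 1]] <- data.frame(
            gene = gene, group = grp, dataset = ds, state = s,
            mean_expr = if (present) mean(x[gene, cells]) else NA_real_,
            detection = if (present) mean(x[gene, cells] > 0) else NA_real_,
            stringsAsFactors = FALSE)
          if (present && !is.null(inv) && s == inv)
            inv_det[gene, ds] <- mean(x[gene, cells] > 0)
        }
      }
    }
  }
  consistency <- apply(inv_det, 1, function(r)
    all(!is.na(r)) && all(r > threshold))
  list(summary = do.call(rbind, rows),
       consistency = data.frame(gene = genes_all,
                                consistent = unname(consistency),
                                stringsAsFactors = FALSE),
       threshold = threshold)
}
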