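#' Pipeline configuration
#'
#' Collects every stage parameter and seed for [run_pipeline()]. The
#' resolved configuration is written as JSON next to the outputs of each
#' run, and round-trips losslessly through [read_pipeline_config()].
#'
#' @param synth Arguments for [synth_config()] (list).
#' @param bulk_noise_sd Log-space noise SD for the synthetic bulk mixtures.
#' @param n_top Variable-gene cap for the encoding.
#' @param lo,hi Concordance filter bounds.
#' @param n_clusters States to cut the cell dendrogram into.
#' @param n_components PCA components.
#' @param marker_top_n Markers per state.
#' @param marker_groups k-means groups on specificity distances.
#' @param nu_grid Nu grid for deconvolution.
#' @param alpha Positive-lasso penalty for imputation.
#' @param drug_classes,drugs_per_class,genes_per_signature,flip_rate
#'   Synthetic drug-signature parameters.
#' @param knn_k Drug-graph neighbours.
#' @param resolution Leiden resolution.
#' @param sens_top_n Drugs flagged per state in the sensitivity rule.
#' @param seed Master seed; stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = list(), bulk_noise_sd = 0.1,
                            n_top = 300, lo = 0.49, hi = 0.51,
                            n_clusters = NULL, n_components = 2,
                            marker_top_n = 80, marker_groups = 10,
                            nu_grid = c(0.25, 0.5, 0.75), alpha = 1e-4,
                            drug_classes = 6, drugs_per_class = 10,
                            genes_per_signature = 80, flip_rate = 0.02,
                            knn_k = 15, resolution = 2.95, sens_top_n = 10,
                            seed = 1, out_dir = tempfile("pairstate_run_")) {
  cfg <- list(synth = synth, bulk_noise_sd = bulk_noise_sd, n_top = n_top,
              lo = lo, hi = hi, n_clusters = n_clusters,
              n_components = n_components, marker_top_n = marker_top_n,
              marker_groups = marker_groups, nu_grid = nu_grid,
              alpha = alpha, drug_classes = drug_classes,
              drugs_per_class = drugs_per_class,
              genes_per_signature = genes_per_signature,
              flip_rate = flip_rate, knn_k = knn_k, resolution = resolution,
              sens_top_n = sens_top_n, seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$synth <- as.list(raw$synth)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage in dependency order on synthetic inputs: simulate
#' single-cell states and bulk mixtures, build the rank-pair encoding,
#' cluster cells and fit the PCA trajectory, project the bulk data, call
#' one-vs-rest differential expression, select markers, build the signature
#' and deconvolve the bulk mixtures, impute state expression, simulate and
#' cluster drug signatures, and run a marker enrichment check against the
#' generating marker sets. All stage outputs are written as plain text under
#' `config$out_dir` together with the resolved configuration, and returned
#' invisibly in memory.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a named list of all stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scfg <- do.call(synth_config,
                  utils::modifyList(list(seed = config$seed), config$synth))

  sim <- step("simulate", simulate_states(scfg))
  bulk <- step("simulate_bulk",
               simulate_bulk(sim$truth, noise_sd = config$bulk_noise_sd,
                             seed = config$seed + 1L))
  enc <- step("encode",
              relative_encoding(sim$cells, bulk$bulk, n_top = config$n_top,
                                lo = config$lo, hi = config$hi))
  t_sc <- step("encode", encode_relative(sim$cells, enc$pairs, "cells"))
  r_bulk <- step("encode", encode_relative(bulk$bulk, enc$pairs, "bulk"))
  k <- if (is.null(config$n_clusters)) scfg$n_states else config$n_clusters
  labels <- step("trajectory", cluster_cells(t_sc, k))
  model <- step("trajectory",
                fit_pca(t_sc, n_components = config$n_components,
                        cluster_labels = labels))
  bulk_coords <- step("project", project_trajectory(model, r_bulk))
  de <- step("de", de_one_vs_rest(sim$cells, labels))
  pc_corr <- step("pc-corr",
                  pc_gene_correlation(sim$cells, model$coordinates, 1))
  markers <- step("markers",
                  select_markers(sim$cells, labels,
                                 top_n = config$marker_top_n,
                                 n_groups = config$marker_groups))
  signature <- step("signature", build_signature(sim$cells, labels, markers))
  props <- step("deconvolve",
                deconvolve_matrix(bulk$bulk, signature,
                                  nu_grid = config$nu_grid))
  imputed <- step("impute",
                  impute_state_expression(
                    expression_matrix(
                      unlog_tpm(em_values(bulk$bulk))[
                        rownames(signature$values), , drop = FALSE], "TPM"),
                    props, alpha = config$alpha))
  sigs <- step("drug-sim",
               simulate_drug_signatures(config$drug_classes,
                                        config$drugs_per_class,
                                        config$genes_per_signature,
                                        universe = rownames(em_values(sim$cells)),
                                        flip_rate = config$flip_rate,
                                        seed = config$seed + 2L))
  D <- step("drug-graph", build_sign_matrix(sigs))
  graph <- step("drug-graph", drug_similarity_graph(D, k = config$knn_k))
  graph <- step("drug-cluster",
                cluster_drugs(graph, resolution = config$resolution,
                              seed = config$seed + 3L))
  enrich <- step("enrich",
                 fisher_enrichment(markers$markers[[1]]$gene,
                                   sim$truth$marker_genes,
                                   universe = rownames(em_values(sim$cells))))

  od <- config$out_dir
  write_pipeline_config(config, file.path(od, "config.json"))
  write_expression(sim$cells, file.path(od, "cells.tsv"))
  write_expression(bulk$bulk, file.path(od, "bulk.tsv"))
  jsonlite::write_json(
    list(state_of_cell = as.list(sim$truth$state_of_cell),
         marker_genes = sim$truth$marker_genes,
         proportions = as.data.frame(bulk$proportions)),
    file.path(od, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write_pairs(enc$pairs, file.path(od, "pairs.tsv"), enc$concordance)
  utils::write.table(data.frame(cell = names(labels), state = labels),
                     file.path(od, "cluster_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(bulk_coords), bulk_coords),
                     file.path(od, "bulk_coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de, file.path(od, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_rnk(pc_corr, file.path(od, "pc1_ranked.rnk"))
  write_markers_gmt(markers, file.path(od, "markers.gmt"))
  utils::write.table(data.frame(gene = rownames(signature$values),
                                signature$values, check.names = FALSE),
                     file.path(od, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(props$proportions),
                                props$proportions,
                                chosen_nu = props$chosen_nu,
                                fit_mse = props$fit_mse, check.names = FALSE),
                     file.path(od, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(imputed$values),
                                imputed$values, check.names = FALSE),
                     file.path(od, "imputed_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(drug = names(graph$clusters),
                                cluster = graph$clusters,
                                class = sigs$moa[names(graph$clusters)]),
                     file.path(od, "drug_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(enrich, file.path(od, "marker_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(config = config, sim = sim, bulk = bulk, encoding = enc,
                 binary_sc = t_sc, binary_bulk = r_bulk, labels = labels,
                 model = model, bulk_coordinates = bulk_coords, de = de,
                 pc_correlation = pc_corr, markers = markers,
                 signature = signature, proportions = props,
                 imputed = imputed, drug_signatures = sigs,
                 drug_graph = graph, enrichment = enrich))
}
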