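toy_signatures <- function() {
  u <- paste0("g", 1:10)
  drug_signature_set(list(
    d1 = list(up = c("g1", "g2"), down = c("g3")),
    d2 = list(up = c("g2"), down = c("g4", "g5")),
    d3 = list(up = character(0), down = character(0)),
    d4 = list(up = c("g1", "g2"), down = c("g3")),
    d5 = list(up = c("g6"), down = c("g7"))), universe = u)
}

test_that("build_sign_matrix encodes up/down/absent and conserves counts", {
  sigs <- toy_signatures()
  D <- build_sign_matrix(sigs)
  expect_equal(unname(D["d1", c("g1", "g3", "g6")]), c(1L, -1L, 0L))
  expect_true(all(D["d3", ] == 0L))           # empty signature: zero row
  # brute-force membership lookup
  for (d in rownames(D)) for (g in colnames(D)) {
    expected <- if (g %in% sigs$drugs[[d]]$up) 1L
                else if (g %in% sigs$drugs[[d]]$down) -1L else 0L
    expect_identical(D[d, g], expected)
  }
  # |up| + |down| conservation
  expect_equal(unname(rowSums(abs(D))),
               vapply(sigs$drugs, function(s) length(s$up) + length(s$down),
                      numeric(1), USE.NAMES = FALSE))
  expect_error(drug_signature_set(list(bad = list(up = "g1", down = "g1")),
                                  paste0("g", 1:3)), "both up and down")
})

test_that("hamming distances match brute force; symmetry and identity hold", {
  set.seed(71)
  D <- matrix(sample(c(-1L, 0L, 1L), 30 * 100, replace = TRUE), 30, 100,
              dimnames = list(sprintf("d%02d", 1:30), NULL))
  g <- drug_similarity_graph(D, k = 5)
  dm <- g$distances
  for (i in 1:30) expect_equal(dm[i, i], 0)
  expect_equal(dm, t(dm))
  oracle <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) oracle[i, j] <- mean(D[i, ] != D[j, ])
  expect_equal(unname(dm), oracle, tolerance = 1e-15)
  # two drugs differing at 3 of 100 positions
  a <- D[1, ]; b <- a; b[c(2, 50, 99)] <- ((a[c(2, 50, 99)] + 2L) %% 3L) - 1L
  D2 <- rbind(x = a, y = b)
  expect_equal(drug_similarity_graph(rbind(D2, D[1:5, ]),
                                     k = 2)$distances["x", "y"], 0.03)
  # neighbour structure: the unique nearest neighbour is always connected,
  # and the connectivity matrix is a symmetric union
  expect_equal(g$connectivities, t(g$connectivities))
  for (i in 1:30) {
    d <- dm[i, -i]
    if (sum(d == min(d)) == 1) {
      nn <- names(which.min(d))
      expect_gt(g$connectivities[i, nn], 0)
    }
  }
  expect_error(drug_similarity_graph(D, k = 30), "smaller")
})

test_that("leiden clustering recovers classes and is seed-deterministic", {
  u <- sprintf("g%03d", 1:600)
  sigs <- simulate_drug_signatures(4, 8, 60, u, flip_rate = 0, seed = 3)
  g <- drug_similarity_graph(build_sign_matrix(sigs), k = 10)
  g1 <- cluster_drugs(g, resolution = 2.95, seed = 9)
  expect_equal(adjusted_rand_index(g1$clusters, sigs$moa), 1)
  g2 <- cluster_drugs(g, resolution = 2.95, seed = 9)
  expect_identical(g1$clusters, g2$clusters)
  expect_true(all(names(g1$clusters) %in% rownames(g$distances)))

  # single drug: one cluster (degenerate graph built directly)
  single <- structure(list(graph = igraph::make_empty_graph(1,
                                                            directed = FALSE) |>
                             igraph::set_vertex_attr("name", value = "only"),
                           distances = matrix(0, 1, 1,
                                              dimnames = list("only", "only")),
                           connectivities = NULL, k = 0, clusters = NULL,
                           embedding = NULL, params = list()),
                      class = "drug_graph")
  expect_equal(unname(cluster_drugs(single, seed = 1)$clusters), 1L)
})

test_that("embedding is seed-deterministic, finite, class-separating", {
  u <- sprintf("g%03d", 1:400)
  sigs <- simulate_drug_signatures(3, 8, 50, u, flip_rate = 0, seed = 4)
  g <- drug_similarity_graph(build_sign_matrix(sigs), k = 8)
  e1 <- embed_drugs(g, seed = 5)
  e2 <- embed_drugs(g, seed = 5)
  expect_identical(e1$embedding, e2$embedding)
  expect_true(all(is.finite(e1$embedding)))
  emb_dist <- as.matrix(dist(e1$embedding))
  expect_gt(silhouette_oracle(emb_dist, sigs$moa[rownames(emb_dist)]), 0)
})

test_that("sensitivity flags, overlaps and rankings match brute force", {
  set.seed(72)
  scores <- matrix(rnorm(50 * 6), 50, 6,
                   dimnames = list(sprintf("drug%02d", 1:50),
                                   paste0("study.state", 1:6)))
  sens <- sensitivity_table(scores, top_n = 10)
  expect_equal(unname(colSums(sens$flags)), rep(10, 6))
  ov <- overlap_matrix(sens)
  expect_equal(ov, t(ov))
  for (a in 1:6) for (b in 1:6)
    expect_equal(ov[a, b],
                 length(intersect(rownames(scores)[sens$flags[, a]],
                                  rownames(scores)[sens$flags[, b]])))
  expect_equal(unname(diag(ov)), rep(10L, 6))

  # identical columns: off-diagonal equals diagonal; disjoint: zero
  dup <- cbind(a = scores[, 1], b = scores[, 1])
  ovd <- overlap_matrix(sensitivity_table(dup, top_n = 10))
  expect_equal(ovd["a", "b"], ovd["a", "a"])
  disj <- cbind(a = c(rep(1, 5), rep(0, 45)), b = c(rep(0, 45), rep(1, 5)))
  rownames(disj) <- rownames(scores)
  expect_equal(overlap_matrix(sensitivity_table(disj, top_n = 5))["a", "b"],
               0L)

  rk <- rank_drugs_by_states(sens)
  expect_equal(sort(rk$n_states, decreasing = TRUE), rk$n_states)
  counts <- rowSums(sens$flags)
  expect_equal(rk$n_states, unname(counts[rk$drug]))
  # all-flagged and never-flagged extremes
  ext <- rbind(hi = c(10, 10), lo = c(0, 0), mid = c(5, 1))
  colnames(ext) <- c("x", "y")
  rk2 <- rank_drugs_by_states(sensitivity_table(ext, top_n = 2))
  expect_equal(rk2$n_states[rk2$drug == "hi"], 2)
  expect_equal(rk2$n_states[rk2$drug == "lo"], 0)
})

test_that("target summary reports group means and consistency", {
  toy <- toy_labelled_matrix()
  x2 <- toy$x * 2
  rownames(x2) <- rownames(toy$x)
  x2 <- x2[c("g1", "g2", "g4", "g5"), ]    # g3 missing from dataset 2
  datasets <- list(
    one = list(matrix = toy$x, labels = toy$labels, invasive_state = "C"),
    two = list(matrix = x2, labels = toy$labels, invasive_state = "B"))
  res <- target_expression_summary(datasets,
                                   list(grp = c("g1", "g2", "g3")),
                                   threshold = 0.1)
  s <- res$summary
  expect_equal(s$mean_expr[s$gene == "g1" & s$dataset == "one" &
                             s$state == "A"],
               mean(toy$x["g1", toy$labels == "A"]))
  expect_true(all(is.na(s$mean_expr[s$gene == "g3" & s$dataset == "two"])))
  cons <- setNames(res$consistency$consistent, res$consistency$gene)
  expect_false(cons["g3"])                      # absent from one dataset
  expect_true(cons["g1"])                       # detected everywhere
  expect_false(cons["g2"])                      # silent in state B of ds one? g2 zero in B cells
})
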