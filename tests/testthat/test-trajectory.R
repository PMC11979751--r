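make_binary <- function(v, pairs = NULL) {
  structure(list(values = v, pairs = pairs, source_id = "test"),
            class = "binary_relative")
}

test_that("cluster_cells recovers planted partitions and degenerate cuts", {
  set.seed(51)
  block <- function(n, p, on) {
    m <- matrix(0, n, p)
    m[, on] <- 1
    m + matrix(rbinom(n * p, 1, 0.02), n, p)
  }
  v <- rbind(block(10, 30, 1:10), block(10, 30, 21:30)) %% 2
  rownames(v) <- sprintf("c%02d", 1:20)
  lab <- cluster_cells(make_binary(v), 2)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(lab[1:10] == lab[1]) && all(lab[11:20] == lab[11]))
  expect_false(lab[1] == lab[11])

  # n_clusters = n cells: every cell its own cluster
  lab_n <- cluster_cells(make_binary(v), 20)
  expect_equal(length(unique(lab_n)), 20)
  expect_error(cluster_cells(make_binary(v), 21), "n_clusters")

  # duplicated rows land together
  v2 <- v[c(1, 1, 11, 11), ]
  rownames(v2) <- paste0("d", 1:4)
  lab2 <- cluster_cells(make_binary(v2), 2)
  expect_equal(lab2[1], lab2[2], ignore_attr = TRUE)
  expect_equal(lab2[3], lab2[4], ignore_attr = TRUE)
})

test_that("fit_pca is a mean-centred PCA with consistent transform", {
  set.seed(52)
  v <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12,
              dimnames = list(sprintf("c%02d", 1:30), NULL))
  model <- fit_pca(make_binary(v), 3)
  # projecting the training matrix reproduces fit coordinates
  expect_equal(project_trajectory(model, make_binary(v)),
               model$coordinates, tolerance = 1e-8)
  expect_lte(sum(model$explained_variance_ratio), 1 + 1e-12)
  expect_error(fit_pca(make_binary(matrix(1, 5, 4)), 2), "variance")
  expect_error(fit_pca(make_binary(v), 13), "n_components")
})

test_that("rank-2 structure is captured and matches an eigen oracle", {
  set.seed(53)
  u1 <- rnorm(40); u2 <- rnorm(40)
  w1 <- rnorm(15); w2 <- rnorm(15)
  v <- outer(u1, w1) + outer(u2, w2)
  rownames(v) <- sprintf("c%02d", 1:40)
  model <- fit_pca(make_binary(v), 3)
  expect_gt(sum(model$explained_variance_ratio[1:2]), 0.999)
  # eigendecomposition of the covariance as an independent oracle
  eig <- eigen(stats::cov(v), symmetric = TRUE)
  expect_equal(model$explained_variance[1:2], eig$values[1:2],
               tolerance = 1e-8)
  for (k in 1:2)   # components equal up to sign
    expect_equal(min(sum((model$components[k, ] - eig$vectors[, k])^2),
                     sum((model$components[k, ] + eig$vectors[, k])^2)),
                 0, tolerance = 1e-12)
})

test_that("projection centres on training means and checks pair lists", {
  set.seed(54)
  pairs <- enumerate_pairs(c("A", "B", "C", "D"))
  x <- matrix(rnorm(4 * 25), 4, 25,
              dimnames = list(c("A", "B", "C", "D"), sprintf("c%02d", 1:25)))
  bin <- encode_relative(x, pairs)
  model <- fit_pca(bin, 2)
  # an observation equal to the training means maps to the origin
  mean_obs <- matrix(model$training_means, 1)
  expect_equal(unname(project_trajectory(model, make_binary(mean_obs))),
               matrix(0, 1, 2), tolerance = 1e-12)
  bad <- encode_relative(x, pairs[c(2, 1, 3:6), ])
  expect_error(project_trajectory(model, bad), "mismatch at pair 1")
})

test_that("projected mixtures of two states fall between their centroids", {
  sim <- small_synth(seed = 12, n_genes = 200, markers_per_state = 25,
                     n_cells_per_state = 40)
  truth <- sim$truth
  # pair filter needs a realistic bulk cohort; the graded mixtures are then
  # encoded on the filtered pairs and projected
  cohort <- simulate_bulk(truth, n_samples = 40, noise_sd = 0.1, seed = 12)
  enc <- relative_encoding(sim$cells, cohort$bulk, n_top = 200)
  P <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
             c(0.75, 0.25, 0, 0), c(0.5, 0.5, 0, 0), c(0.25, 0.75, 0, 0))
  bulk <- simulate_bulk(truth, noise_sd = 0, seed = 12, proportions = P)
  t_sc <- encode_relative(sim$cells, enc$pairs)
  model <- fit_pca(t_sc, 2)
  coords <- project_trajectory(model, encode_relative(bulk$bulk, enc$pairs))
  labels <- truth$state_of_cell
  cent <- vapply(c("state1", "state2"), function(s)
    colMeans(model$coordinates[labels == s, , drop = FALSE]), numeric(2))
  # orient PC1 so state1 < state2, then mixtures must lie inside the span
  sgn <- sign(cent[1, "state2"] - cent[1, "state1"])
  pc1 <- coords[, 1] * sgn
  lo <- cent[1, "state1"] * sgn; hi <- cent[1, "state2"] * sgn
  expect_true(all(pc1[3:5] > lo & pc1[3:5] < hi))
  # mixture coordinate ordered by mixing weight
  expect_true(all(diff(pc1[3:5]) > 0) || all(diff(pc1[3:5]) < 0))
})

test_that("de_one_vs_rest matches rank-sum oracle and Bonferroni", {
  x <- rbind(g1 = c(8, 9, 10, 11, 1, 2, 3, 4, 5, 6),
             g2 = rep(3, 10),
             g3 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  colnames(x) <- paste0("c", 1:10)
  labels <- rep(c("A", "B"), c(4, 6))
  de <- de_one_vs_rest(x, labels, test = "wilcoxon")
  g1A <- de[de$gene == "g1" & de$state == "A", ]
  # exhaustive rank oracle: W = sum of A-ranks - n1(n1+1)/2
  r <- rank(x["g1", ])
  expect_equal(g1A$statistic, sum(r[1:4]) - 4 * 5 / 2)
  expect_equal(g1A$p, stats::wilcox.test(x["g1", 1:4], x["g1", 5:10],
                                         exact = TRUE)$p.value)
  # Hodges-Lehmann location: median of all pairwise differences
  expect_equal(g1A$location,
               median(outer(x["g1", 1:4], x["g1", 5:10], "-")))
  # constant gene: p = 1, never significant
  g2A <- de[de$gene == "g2" & de$state == "A", ]
  expect_equal(g2A$p, 1)
  expect_false(g2A$significant)
  # Bonferroni: 3 genes x 2 states
  expect_equal(de$p_adj, pmin(1, de$p * 6))
  expect_true(all(de$p_adj >= de$p))
})

test_that("DE is symmetric under swapping state and rest", {
  set.seed(55)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12)))
  labels <- rep(c("A", "B"), each = 6)
  de <- de_one_vs_rest(x, labels)
  a <- de[de$state == "A", ]; b <- de[de$state == "B", ]
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$location, -b$location, tolerance = 1e-12)
  expect_equal(a$direction, -b$direction)
  expect_error(de_one_vs_rest(x, c("A", rep("B", 11))), "fewer than 2")
})

test_that("t-test mode reports mean shifts", {
  set.seed(56)
  x <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:20)))
  x[1, 1:10] <- x[1, 1:10] + 3
  labels <- rep(c("A", "B"), each = 10)
  de <- de_one_vs_rest(x, labels, test = "ttest")
  row <- de[de$gene == "g1" & de$state == "A", ]
  ht <- t.test(x[1, 1:10], x[1, 11:20])
  expect_equal(row$p, ht$p.value)
  expect_equal(row$location, mean(x[1, 1:10]) - mean(x[1, 11:20]))
})

test_that("pc_gene_correlation matches a rank-then-Pearson oracle", {
  set.seed(57)
  pc <- rnorm(20)
  x <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:20)))
  x[1, ] <- pc            # rho = 1
  x[2, ] <- -pc           # rho = -1
  res <- pc_gene_correlation(x, matrix(pc, ncol = 1), 1, alpha = 1.01)
  full <- attr(res, "full")
  expect_equal(full$rho[full$gene == "g1"], 1)
  expect_equal(full$rho[full$gene == "g2"], -1)
  expect_equal(full$gene[1], "g1")                 # most positive first
  expect_equal(full$gene[nrow(full)], "g2")        # most negative last
  oracle <- apply(x, 1, function(r) stats::cor(rank(r), rank(pc)))
  expect_equal(full$rho[match(names(oracle), full$gene)],
               unname(oracle), tolerance = 1e-12)
  expect_error(pc_gene_correlation(x, rep(1, 20), 1), "constant")
})

test_that("crosstab_state_proportions equals brute-force counting", {
  a <- c("x", "x", "y", "y")
  expect_equal(unname(diag(crosstab_state_proportions(a, a))), c(1, 1))

  set.seed(58)
  la <- sample(paste0("s", 1:5), 200, replace = TRUE)
  lj <- sample(paste0("j", 1:6), 200, replace = TRUE)
  prop <- crosstab_state_proportions(la, lj)
  expect_equal(unname(rowSums(prop)), rep(1, 5), tolerance = 1e-12)
  for (s in rownames(prop)) for (j in colnames(prop))
    expect_equal(prop[s, j], sum(la == s & lj == j) / sum(la == s))
  expect_error(crosstab_state_proportions(la, lj[-1]), "length")
})

test_that("encode-then-cluster recovers the generating states", {
  sim <- small_synth(seed = 13)
  bulk <- simulate_bulk(sim$truth, n_samples = 40, noise_sd = 0.1, seed = 13)
  enc <- relative_encoding(sim$cells, bulk$bulk, n_top = 300)
  lab <- cluster_cells(encode_relative(sim$cells, enc$pairs), 4)
  expect_gt(adjusted_rand_index(lab, sim$truth$state_of_cell), 0.9)
})
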