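# Independent oracle implementations used across test files. Deliberately
# brute-force / closed-form and kept separate from the package code paths.

# Adjusted Rand index between two labellings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Lawson-Hanson style non-negative least squares by active set; independent
# of the quadprog-based nu-SVR path.
nnls_oracle <- function(X, y, max_iter = 200) {
  p <- ncol(X)
  passive <- rep(FALSE, p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    w <- drop(t(X) %*% (y - X %*% beta))
    w[passive] <- -Inf
    if (all(w <= 1e-10)) break
    passive[which.max(w)] <- TRUE
    repeat {
      s <- rep(0, p)
      s[passive] <- drop(solve(crossprod(X[, passive, drop = FALSE]),
                               crossprod(X[, passive, drop = FALSE], y)))
      if (all(s[passive] > 0)) { beta <- s; break }
      idx <- passive & s <= 0
      alpha <- min(beta[idx] / (beta[idx] - s[idx]))
      beta <- beta + alpha * (s - beta)
      passive[beta <= 1e-12 & passive] <- FALSE
      beta[!passive] <- 0
    }
  }
  beta
}

# Exhaustive optimal 1-D k-means: enumerate all contiguous partitions of the
# sorted values (the optimum is contiguous). Only for small n.
kmeans_1d_oracle <- function(x, k) {
  n <- length(x)
  s <- sort(x)
  best <- list(cost = Inf)
  boundaries <- utils::combn(n - 1, k - 1)
  for (col in seq_len(ncol(boundaries))) {
    cuts <- c(0, boundaries[, col], n)
    cost <- 0
    for (m in seq_len(k)) {
      blk <- s[(cuts[m] + 1):cuts[m + 1]]
      cost <- cost + sum((blk - mean(blk))^2)
    }
    if (cost < best$cost) best <- list(cost = cost, cuts = cuts)
  }
  cl_sorted <- rep(seq_len(k), diff(best$cuts))
  cl <- integer(n)
  cl[order(x)] <- cl_sorted
  list(cluster = cl, withinss = best$cost)
}

# One-sided hypergeometric upper tail by explicit combinatorics:
# P(overlap >= a) for a query of size q, set of size m, universe of size N.
hyper_tail_oracle <- function(a, q, m, N) {
  ks <- a:min(q, m)
  sum(exp(lchoose(m, ks) + lchoose(N - m, q - ks) - lchoose(N, q)))
}

# Mean silhouette width for labelled points from a distance matrix.
silhouette_oracle <- function(dist_mat, labels) {
  labels <- as.character(labels)
  n <- nrow(dist_mat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(dist_mat[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dist_mat[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small labelled expression fixture: 3 states x 4 cells, 5 genes.
toy_labelled_matrix <- function() {
  set.seed(11)
  x <- matrix(stats::rexp(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:12)))
  x[1, 1:4] <- x[1, 1:4] + 5        # g1 elevated in state A
  x[2, 5:8] <- 0                    # g2 silent in state B
  list(x = x, labels = rep(c("A", "B", "C"), each = 4))
}

small_synth <- function(seed = 7, ...) {
  defaults <- list(n_genes = 300, markers_per_state = 30,
                   n_cells_per_state = 60, seed = seed)
  cfg <- do.call(synth_config, utils::modifyList(defaults, list(...)))
  simulate_states(cfg)
}
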