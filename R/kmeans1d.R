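#' Optimal 1-D k-means by dynamic programming
#'
#' Exact minimiser of the within-cluster sum of squares for one-dimensional
#' data. The optimum partitions the sorted values into contiguous blocks, so
#' it can be found by dynamic programming over block boundaries (the
#' Ckmeans.1d.dp algorithm). Deterministic, unlike Lloyd iterations with
#' random restarts.
#'
#' @param x Numeric vector.
#' @param k Number of clusters (k <= length(x)).
#' @return List with `cluster` (assignment per element of `x`, clusters
#'   numbered by increasing centre), `centers`, and `withinss` (total).
#' @export
kmeans_1d <- function(x, k) {
  n <- length(x)
  if (k < 1 || k > n) stop("k must be between 1 and length(x)")
  ord <- order(x)
  s <- x[ord]
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  # cost of block i..j (1-based, inclusive): ss - sum^2 / len
  block_cost <- function(i, j) {
    sm <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    pmax(s2 - sm^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)      # D[m, j]: best cost of first j points in m blocks
  B <- matrix(0L, k, n)       # start index of last block
  D[1, ] <- vapply(seq_len(n), function(j) block_cost(1, j), numeric(1))
  B[1, ] <- 1L
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j                              # candidate starts of last block
        sm <- cs[j] - cs[i - 1]
        s2 <- cs2[j] - cs2[i - 1]
        costs <- D[m - 1, i - 1] + pmax(s2 - sm^2 / (j - i + 1), 0)
        best <- which.min(costs)
        D[m, j] <- costs[best]
        B[m, j] <- i[best]
      }
    }
  }
  # backtrack
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (m in k:1) {
    bounds[m] <- B[m, j] - 1L
    j <- B[m, j] - 1L
  }
  cluster_sorted <- rep(seq_len(k), diff(bounds))
  cluster <- integer(n)
  cluster[ord] <- cluster_sorted
  centers <- vapply(seq_len(k),
                    function(m) mean(s[(bounds[m] + 1):bounds[m + 1]]),
                    numeric(1))
  list(cluster = cluster, centers = centers, withinss = D[k, n])
}
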