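# Independent oracles used across test files. These recompute quantities by
# direct enumeration / summation, never through the package's own code paths.

# Total within-cluster SSE of a partition, by direct summation.
brute_sse <- function(x, clusters) {
  sum(vapply(clusters, function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }, numeric(1)))
}

# Ward agglomeration by exhaustive evaluation of every candidate merge at
# every step, with delta-SSE computed from the raw points. Returns the
# partition (list of index sets) at each cluster count n..1 and the
# delta-SSE of each merge.
brute_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- as.list(seq_len(nrow(x)))
  partitions <- list()
  partitions[[length(clusters)]] <- clusters
  deltas <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      merged <- c(clusters[[a]], clusters[[b]])
      d <- brute_sse(x, list(merged)) -
        brute_sse(x, clusters[c(a, b)])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(a, b) }
    }
    deltas <- c(deltas, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
    partitions[[length(clusters)]] <- clusters
  }
  list(partitions = partitions, deltas = deltas)
}

# Are two labelings the same partition (up to label names)?
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(ta > 0) == max(length(unique(a)), length(unique(b)))
}

partition_labels <- function(clusters, n) {
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Small complete toy population: two countries, two sharply separated
# answer patterns, no missing values.
toy_population <- function(n_a = 40, n_b = 40, seed = 42) {
  set.seed(seed)
  high <- function(n) matrix(sample(4:5, n * 5, TRUE), n, 5)
  low <- function(n) matrix(sample(1:2, n * 3, TRUE), n, 3)
  mid <- function(n) matrix(sample(2:3, n * 5, TRUE), n, 5)
  items <- rbind(cbind(high(n_a), low(n_a)),
                 cbind(mid(n_b), low(n_b)))
  response_matrix(items, rep(c("AAA", "BBB"), c(n_a, n_b)))
}
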