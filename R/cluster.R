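#' Ward agglomerative clustering
#'
#' Agglomerates points by Ward's minimum-variance criterion: at every step
#' the merge chosen is the one with the smallest increase in total
#' within-cluster sum of squared Euclidean distances. The tree is cut at
#' `k` clusters.
#'
#' @param features Numeric matrix of finite feature vectors.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer label vector in `1..k`. The `hclust` tree is attached as
#'   attribute `"tree"` (merge heights equal `sqrt(2 * delta-SSE)`).
#' @export
ward_cluster <- function(features, k) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite feature values")
  n <- nrow(features)
  if (k < 1L || k > n) stop("k must be in 1..n (n = ", n, ")")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Pooled within-cluster dispersion
#'
#' `W = sum over clusters of sum over members of ||x - centroid||^2`; the
#' quantity whose log the gap statistic compares against structureless
#' reference data.
#'
#' @param features Numeric feature matrix.
#' @param labels Cluster labels (any label set; each must be non-empty).
#' @return Non-negative scalar; 0 iff every cluster is a point mass.
#' @export
within_dispersion <- function(features, labels) {
  features <- as.matrix(features)
  stopifnot(length(labels) == nrow(features))
  if (anyNA(labels)) stop("empty (NA) cluster label")
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    x <- features[idx, , drop = FALSE]
    sum(sweep(x, 2L, colMeans(x))^2)
  }, numeric(1)))
}

#' Gap statistic for choosing the number of response types
#'
#' For each candidate `k`, compares the log within-cluster dispersion of
#' Ward clusterings of the data with its average over `B` reference
#' datasets drawn uniformly over the observed per-coordinate ranges
#' (structureless data of the same shape):
#' `gap(k) = mean_b log W_k(ref_b) - log W_k(data)`. The per-k simulation
#' spread is `s_k = sd_b(log W_k(ref_b)) * sqrt(1 + 1/B)`. The selected `k`
#' is the smallest with `gap(k) >= gap(k+1) - s(k+1)` (the one-standard-error
#' rule); if no `k` qualifies the argmax of the gap is used. The full curve
#' is returned so the elbow can be inspected.
#'
#' @param features Numeric feature matrix.
#' @param k_range Integer vector of candidate cluster numbers; default 2..12.
#' @param B Number of reference datasets; default 50.
#' @param seed Integer RNG seed for the reference draws.
#' @return An object of class `gap_curve`: data frame fields `k`, `log_W`,
#'   `gap`, `s`, plus `B` and `selected_k`.
#' @export
gap_statistic <- function(features, k_range = 2:12, B = 50L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("k_range is empty")
  if (any(k_range < 1L) || any(k_range >= n))
    stop("k_range must lie in [1, n)")
  rng <- apply(features, 2L, range)
  if (any(rng[2L, ] - rng[1L, ] <= 0))
    stop("degenerate (zero-range) feature column")
  logW_path <- function(x) {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    cuts <- stats::cutree(hc, k = k_range)
    if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1L)
    log(vapply(seq_along(k_range), function(j)
      within_dispersion(x, cuts[, j]), numeric(1)))
  }
  log_W <- logW_path(features)
  set.seed(as.integer(seed))
  ref <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    x <- vapply(seq_len(ncol(features)), function(j)
      stats::runif(n, rng[1L, j], rng[2L, j]), numeric(n))
    ref[b, ] <- logW_path(x)
  }
  gap <- colMeans(ref) - log_W
  s <- apply(ref, 2L, stats::sd) * sqrt(1 + 1 / B)
  sel <- NA_integer_
  if (length(k_range) > 1L) {
    ok <- which(gap[-length(gap)] >= gap[-1L] - s[-1L])
    if (length(ok)) sel <- k_range[ok[1L]]
  }
  if (is.na(sel)) sel <- k_range[which.max(gap)]
  structure(list(k = k_range, log_W = log_W, gap = gap, s = s,
                 B = as.integer(B), selected_k = sel),
            class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat("Gap-statistic curve (B =", x$B, "reference draws)\n")
  print(data.frame(k = x$k, log_W = x$log_W, gap = x$gap, s = x$s),
        row.names = FALSE, digits = 4)
  cat("selected k:", x$selected_k, "\n")
  invisible(x)
}

#' Extract response-type profiles from a clustering
#'
#' Summarises each cluster as a response type: mean and SD of every main
#' item and of the discrimination score, over the cluster's members.
#' Summaries are computed on the un-jittered features so that the reported
#' means are not noise-shifted; profiles are ordered by descending
#' discrimination mean (ties by climate-change mean) and numbered 1..k in
#' that order.
#'
#' @param features Un-jittered `n x 6` feature matrix (5 main items +
#'   discrimination).
#' @param labels Cluster labels from [ward_cluster()].
#' @param schema An [item_schema()].
#' @return Data frame in the layout of `load_fixture("table2")`, plus a
#'   `size` column; attribute `"relabel"` maps input label -> `type_id`.
#' @export
extract_profiles <- function(features, labels, schema = item_schema()) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  groups <- split(seq_along(labels), labels)
  rows <- lapply(groups, function(idx) {
    x <- features[idx, , drop = FALSE]
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[is.na(sdv)] <- 0          # singleton cluster
    out <- list()
    for (it in schema$main_items) {
      out[[paste0(it, "_mean")]] <- unname(mu[it])
      out[[paste0(it, "_sd")]] <- unname(sdv[it])
    }
    out$discrimination_mean <- unname(mu["discrimination"])
    out$discrimination_sd <- unname(sdv["discrimination"])
    out$size <- length(idx)
    as.data.frame(out)
  })
  prof <- do.call(rbind, rows)
  ord <- order(-prof$discrimination_mean, -prof$climate_change_mean)
  prof <- prof[ord, , drop = FALSE]
  prof <- cbind(type_id = seq_len(nrow(prof)), prof)
  rownames(prof) <- NULL
  relabel <- stats::setNames(order(ord), names(groups))
  attr(prof, "relabel") <- relabel
  prof
}

# Exact minimum-cost assignment by dynamic programming over column subsets.
# Cost is an n x n matrix; returns the row -> column permutation.
min_cost_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 20L)
  nstates <- bitwShiftL(1L, n)
  best <- rep(Inf, nstates)
  choice <- matrix(NA_integer_, n, nstates)
  best[1L] <- 0
  for (state in seq_len(nstates) - 1L) {
    if (!is.finite(best[state + 1L])) next
    i <- sum(bitwAnd(state, bitwShiftL(1L, 0:(n - 1L))) != 0L) + 1L
    if (i > n) next
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(state, bit) != 0L) next
      ns <- bitwOr(state, bit)
      v <- best[state + 1L] + cost[i, j]
      if (v < best[ns + 1L]) { best[ns + 1L] <- v; choice[i, ns + 1L] <- j }
    }
  }
  perm <- integer(n)
  state <- nstates - 1L
  for (i in n:1) {
    j <- choice[i, state + 1L]
    perm[i] <- j
    state <- bitwAnd(state, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  perm
}

#' Match estimated profiles to reference profiles
#'
#' The numbering of clusters is arbitrary, so estimated response types are
#' aligned with a reference set (e.g. the published profile table) by the
#' assignment minimising the total Euclidean distance between profile
#' centroid vectors (the 5 main-item means plus the discrimination mean).
#' The assignment is globally optimal, not greedy.
#'
#' @param profiles,reference Data frames in the layout returned by
#'   [extract_profiles()] / `load_fixture("table2")`; equal row counts.
#' @return Data frame with `profile_id`, `reference_id` and the centroid
#'   `distance` of each matched pair.
#' @export
match_profiles <- function(profiles, reference) {
  if (nrow(profiles) != nrow(reference))
    stop("profile count ", nrow(profiles), " != reference count ",
         nrow(reference))
  cols <- c(paste0(item_schema()$main_items, "_mean"), "discrimination_mean")
  a <- as.matrix(profiles[, cols])
  b <- as.matrix(reference[, cols])
  cost <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                              nrow(a) + seq_len(nrow(b))]
  perm <- min_cost_assignment(cost)
  data.frame(profile_id = profiles$type_id,
             reference_id = reference$type_id[perm],
             distance = cost[cbind(seq_along(perm), perm)])
}
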