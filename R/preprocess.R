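#' Preprocessing configuration
#'
#' @param n_neighbors Number of nearest neighbours used to impute each
#'   missing cell; default 8.
#' @param jitter_variance Variance of the zero-mean Gaussian perturbation
#'   applied to each feature coordinate before clustering; default 0.001.
#' @param seed Integer seed for the jitter stream.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_neighbors = 8L, jitter_variance = 0.001,
                              seed = 20200901) {
  stopifnot(n_neighbors >= 1L, jitter_variance >= 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 jitter_variance = jitter_variance,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' KNN imputation over co-observed items
#'
#' Each missing cell is replaced by the unweighted mean of that item over
#' the `n_neighbors` nearest questionnaires that observed it. Closeness of
#' two questionnaires is measured only over the items both observed:
#' Euclidean distance over the co-observed items, rescaled by
#' `sqrt(n_items / n_co_observed)` so that sparser overlaps are not
#' spuriously close. Observed cells are never altered; ties in distance are
#' broken by the lower row index.
#'
#' @param mat A [response_matrix()] (or numeric item matrix).
#' @param config A [preprocess_config()]; only `n_neighbors` is used.
#' @return The input with every missing cell imputed (values lie in
#'   `[1, 5]` since they are means of observed Likert values).
#' @export
impute_knn <- function(mat, config = preprocess_config()) {
  is_rm <- inherits(mat, "response_matrix")
  items <- if (is_rm) mat$items else as.matrix(mat)
  n <- nrow(items); p <- ncol(items)
  k <- config$n_neighbors
  miss <- is.na(items)
  if (!any(miss)) return(mat)
  if (any(rowSums(miss) == p))
    stop("record ", which(rowSums(miss) == p)[1], " has all items missing")
  if (n < k + 1L)
    stop("need at least n_neighbors + 1 = ", k + 1L, " records, have ", n)
  obs <- !miss
  out <- items
  for (i in which(rowSums(miss) > 0L)) {
    cols <- which(obs[i, ])
    sub <- items[, cols, drop = FALSE]
    subobs <- obs[, cols, drop = FALSE]
    delta <- sweep(sub, 2L, items[i, cols])
    delta[!subobs] <- 0
    co <- rowSums(subobs)                  # co-observed count vs every row
    d <- sqrt(p / pmax(co, 1)) * sqrt(rowSums(delta^2))
    d[co == 0] <- Inf
    d[i] <- Inf
    for (j in which(miss[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (!length(cand))
        stop("no neighbour observes item '", colnames(items)[j],
             "' for record ", i)
      ord <- cand[order(d[cand], cand)]    # distance, then row index
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(items[nb, j])
    }
  }
  if (is_rm) { mat$items <- out; mat } else out
}

#' Engineer 6-dimensional feature vectors
#'
#' Replaces the three minor-driver items by a single discrimination score
#' `D = mean(main items) - mean(minor items)`, so each questionnaire becomes
#' a 6-dimensional vector: the five main-item ratings plus `D`. High `D`
#' means the respondent separates real drivers from distractors; `D` lies in
#' `[-4, 4]` for Likert items in 1..5.
#'
#' @param mat A complete (post-imputation) [response_matrix()] or item
#'   matrix.
#' @param schema An [item_schema()]; ignored when `mat` carries its own.
#' @return Numeric matrix `n x 6` with columns the main items and
#'   `"discrimination"`.
#' @export
engineer_features <- function(mat, schema = item_schema()) {
  if (inherits(mat, "response_matrix")) { schema <- mat$schema; mat <- mat$items }
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("feature engineering requires a complete matrix; impute first")
  main <- mat[, schema$main_items, drop = FALSE]
  minor <- mat[, schema$minor_items, drop = FALSE]
  D <- rowMeans(main) - rowMeans(minor)
  cbind(main, discrimination = D)
}

#' Seeded Gaussian jitter
#'
#' Adds i.i.d. Gaussian noise with mean zero and the configured variance to
#' every coordinate, so that duplicated questionnaires become distinct (a
#' numerical-stability requirement of the agglomerative clustering) without
#' moving any point materially. One seeded stream is consumed in row-major
#' order, so results are reproducible but depend on row order.
#'
#' @param features Numeric matrix of engineered features.
#' @param config A [preprocess_config()]; uses `jitter_variance` and `seed`.
#' @return The perturbed matrix; the identity when the variance is 0.
#' @export
jitter_features <- function(features, config = preprocess_config()) {
  features <- as.matrix(features)
  if (config$jitter_variance == 0) return(features)
  set.seed(config$seed)
  noise <- matrix(stats::rnorm(length(features),
                               sd = sqrt(config$jitter_variance)),
                  nrow = nrow(features), byrow = TRUE)
  features + noise
}
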