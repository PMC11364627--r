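#' Fingerprint set constructor
#'
#' A fingerprint summarises a country as the vector of proportions of each
#' response type among its respondents; rows therefore live on the
#' probability simplex.
#'
#' @param matrix Numeric `countries x k` matrix of proportions.
#' @param countries Character vector of country codes, one per row.
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(matrix, countries) {
  matrix <- as.matrix(matrix)
  countries <- toupper(as.character(countries))
  stopifnot(nrow(matrix) == length(countries))
  if (anyDuplicated(countries)) stop("duplicate country codes")
  if (any(matrix < -1e-12) || any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("fingerprint rows must be non-negative and sum to 1")
  rownames(matrix) <- countries
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("type_", seq_len(ncol(matrix)))
  structure(list(countries = countries, matrix = matrix),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprints: ", length(x$countries), " countries x ",
      ncol(x$matrix), " response types\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Compute country fingerprints from cluster labels
#'
#' Entry `(c, i)` is the share of country `c`'s respondents assigned to
#' response type `i`. Countries below the minimum sample size are excluded
#' (they still contributed to the clustering itself).
#'
#' @param labels Integer type labels in `1..k`, one per respondent.
#' @param countries Country code per respondent.
#' @param k Number of response types.
#' @param min_country_n Minimum respondents a country needs to receive a
#'   fingerprint; default 25. Excluded countries are reported via a warning
#'   and the `"excluded"` attribute.
#' @return A [fingerprint_set()].
#' @export
compute_fingerprints <- function(labels, countries, k,
                                 min_country_n = 25L) {
  stopifnot(length(labels) == length(countries))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > k)) stop("labels must lie in 1..k")
  countries <- toupper(as.character(countries))
  tab <- table(countries)
  keep <- names(tab)[tab >= min_country_n]
  dropped <- setdiff(names(tab), keep)
  if (!length(keep)) stop("no country reaches the minimum sample size")
  if (length(dropped))
    warning("excluded below minimum sample size (", min_country_n, "): ",
            paste(dropped, collapse = ", "))
  m <- t(vapply(keep, function(cc) {
    tabulate(labels[countries == cc], nbins = k) / sum(countries == cc)
  }, numeric(k)))
  colnames(m) <- paste0("type_", seq_len(k))
  fp <- fingerprint_set(m, keep)
  attr(fp, "excluded") <- dropped
  fp
}

#' Euclidean distances between country fingerprints
#'
#' @param set A [fingerprint_set()] with at least 2 countries.
#' @return Symmetric distance matrix with zero diagonal, country codes as
#'   dimnames.
#' @export
fingerprint_distance <- function(set) {
  stopifnot(inherits(set, "fingerprint_set"))
  if (length(set$countries) < 2L) stop("need at least 2 countries")
  as.matrix(stats::dist(set$matrix))
}

#' Ward dendrogram of countries
#'
#' Clusters countries by Ward's method on their fingerprint vectors, so
#' countries whose respondents distribute similarly over the response types
#' join early. Branch lengths follow the ultrametric convention: each merge
#' height is split in half onto the two child branches.
#'
#' @param set A [fingerprint_set()] with at least 2 countries.
#' @return An object of class `country_tree`: the `hclust` object, the
#'   `ape::phylo` tree, and its Newick string.
#' @export
country_dendrogram <- function(set) {
  stopifnot(inherits(set, "fingerprint_set"))
  if (length(set$countries) < 2L) stop("need at least 2 countries")
  hc <- stats::hclust(stats::dist(set$matrix), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)),
            class = "country_tree")
}

#' @export
print.country_tree <- function(x, ...) {
  cat("Ward dendrogram of", length(x$hclust$labels), "countries\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a country tree as Newick
#'
#' @param tree A `country_tree` from [country_dendrogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "country_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
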