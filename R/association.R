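#' Spearman rank correlation with two-sided p value
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' average-ranked values (ties receive average ranks). The default p value
#' is the usual two-sided t approximation with `n - 2` degrees of freedom,
#' `t = r * sqrt((n - 2) / (1 - r^2))`; for small samples (`n <= 9`) an
#' exact permutation p value — the share of the `n!` rank permutations with
#' `|r|` at least as large as observed — is available for audit.
#'
#' @param x,y Numeric vectors of equal length `>= 5`, each non-constant.
#' @param exact If `TRUE` (only allowed for `n <= 9`), return the exact
#'   permutation p value instead of the t approximation.
#' @return List with `r`, `p`, `n`, `method`.
#' @examples
#' spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))$r  # 0.9486833
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact permutation p restricted to n <= 9")
    perms <- permutations_of(n)
    # r is affine in the permuted cross-sum, so all n! values come from one
    # matrix product
    cross <- matrix(ry[perms], nrow(perms)) %*% rx
    rs <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(r = r, p = p, n = n, method = method)
}

# All n! permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Flag a correlation cell
#'
#' A cell is *moderate* when `|r| > 0.3` and *significant* when
#' `p <= 0.05`; the screen highlights cells that are both.
#'
#' @param r,p Numeric vectors.
#' @return Data frame with logical `moderate`, `significant`, `flagged`.
#' @export
flag_cells <- function(r, p) {
  data.frame(moderate = abs(r) > 0.3,
             significant = p <= 0.05,
             flagged = abs(r) > 0.3 & p <= 0.05)
}

#' Correlate fingerprint components with country indices
#'
#' For every (response type, index) pair, computes the Spearman correlation
#' between the proportion of that type across countries and the index, over
#' the countries present in both tables (inner join). No multiple-testing
#' adjustment is applied by default, matching the screening character of the
#' analysis; `adjust = "BH"` applies Benjamini-Hochberg across all cells.
#'
#' @param set A [fingerprint_set()].
#' @param index_table Data frame from [read_index_table()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `association_table`: `cells` (data frame with
#'   `type_id`, `index`, `r`, `p`, flags, `n_countries`) and `countries`
#'   used.
#' @export
correlate_fingerprints <- function(set, index_table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(set, "fingerprint_set"))
  common <- intersect(set$countries, toupper(index_table$country))
  if (length(common) < 5L)
    stop("need at least 5 countries present in both tables, have ",
         length(common))
  fp <- set$matrix[common, , drop = FALSE]
  idx <- index_table[match(common, toupper(index_table$country)), ]
  index_names <- setdiff(names(idx), "country")
  cells <- do.call(rbind, lapply(seq_len(ncol(fp)), function(i) {
    do.call(rbind, lapply(index_names, function(nm) {
      sp <- spearman(fp[, i], idx[[nm]])
      data.frame(type_id = i, index = nm, r = sp$r, p = sp$p,
                 n_countries = sp$n)
    }))
  }))
  if (adjust == "BH") cells$p <- stats::p.adjust(cells$p, method = "BH")
  cells <- cbind(cells, flag_cells(cells$r, cells$p))
  structure(list(cells = cells, countries = common),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("Spearman screen over", length(x$countries), "countries;",
      sum(x$cells$flagged), "flagged cells (|r| > 0.3 and p <= 0.05)\n")
  print(x$cells, row.names = FALSE, digits = 3)
  invisible(x)
}
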