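# Discretised-Gaussian machinery: a latent Gaussian(mu, sigma) is binned onto
# the Likert grid {1..5} (unit bins centred on each level, tails folded into
# 1 and 5). Moment matching makes printed profile means recoverable from
# simulated integer responses despite the coarse grid.

# Bin masses of N(mu, sigma) on {1..5}; boundaries at 1.5, 2.5, 3.5, 4.5.
likert_bin_masses <- function(mu, sigma) {
  cuts <- c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
  p <- diff(stats::pnorm(cuts, mean = mu, sd = sigma))
  p / sum(p)
}

likert_moments <- function(mu, sigma) {
  p <- likert_bin_masses(mu, sigma)
  m <- sum(p * (1:5))
  v <- sum(p * (1:5)^2) - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Match a discretised-Gaussian item distribution to a target mean and SD
#'
#' Finds latent Gaussian parameters `(mu, sigma)` such that the distribution
#' obtained by discretising N(mu, sigma) onto the Likert grid 1..5 has mean
#' within 0.01 of `target_mean`, and SD as close to `target_sd` as the grid
#' allows. The discrete mean is monotone in `mu` at fixed `sigma`, so `mu` is
#' solved by root finding inside a one-dimensional search over `sigma`.
#'
#' @param target_mean Target item mean, in `[1, 5]`.
#' @param target_sd Target item SD, `> 0`.
#' @param tol Required absolute accuracy on the achieved mean (default 0.01).
#' @return List with `mu`, `sigma`, `achieved_mean`, `achieved_sd`.
#' @examples
#' match_discrete_params(3, 1)$mu  # 3 by symmetry
#' @export
match_discrete_params <- function(target_mean, target_sd, tol = 0.01) {
  stopifnot(target_mean >= 1, target_mean <= 5, target_sd > 0)
  mu_for_mean <- function(sigma) {
    f <- function(mu) likert_moments(mu, sigma)[["mean"]] - target_mean
    lo <- -20; hi <- 26
    if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  sd_gap <- function(sigma) {
    mu <- mu_for_mean(sigma)
    if (is.na(mu)) return(Inf)
    abs(likert_moments(mu, sigma)[["sd"]] - target_sd)
  }
  opt <- stats::optimize(sd_gap, interval = c(0.02, 4))
  sigma <- opt$minimum
  mu <- mu_for_mean(sigma)
  if (is.na(mu)) { sigma <- max(target_sd, 0.2); mu <- mu_for_mean(sigma) }
  got <- likert_moments(mu, sigma)
  if (is.na(mu) || abs(got[["mean"]] - target_mean) > tol)
    stop(sprintf(
      "infeasible target (mean %.3f, sd %.3f): achieved mean %.4f",
      target_mean, target_sd, if (is.na(mu)) NA else got[["mean"]]))
  list(mu = mu, sigma = sigma,
       achieved_mean = got[["mean"]], achieved_sd = got[["sd"]])
}

# Draw n Likert values from the matched discrete distribution.
sample_likert <- function(n, mu, sigma) {
  sample.int(5L, n, replace = TRUE, prob = likert_bin_masses(mu, sigma))
}

#' Generator configuration for synthetic questionnaire populations
#'
#' The generator draws each respondent's response type from their country's
#' mixing proportions, then draws the eight item ratings independently from
#' the type's matched discretised-Gaussian item distributions, and finally
#' deletes cells completely at random. Defaults reproduce the study
#' conditions the profile table describes: the eight published response-type
#' profiles, with the three minor items sharing one distribution whose mean
#' is `mean(main means) - discrimination_mean` and whose SD is the
#' discrimination SD (no per-minor-item parameters are published).
#'
#' @param profiles Data frame in the layout of `load_fixture("table2")`.
#' @param country_fingerprints Named list: country code -> numeric vector of
#'   mixing proportions over the profiles (each summing to 1). Default: one
#'   country `"SYN"` with an equal mixture over the eight profiles.
#' @param n_per_country Named integer vector of respondents per country.
#'   Default 4000 for the single default country (500 per profile).
#' @param missing_rate MCAR cell-deletion probability in `[0, 1)`;
#'   default 0.02.
#' @param seed Integer RNG seed; default 20200901.
#' @param schema An [item_schema()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(profiles = load_fixture("table2"),
                             country_fingerprints = NULL,
                             n_per_country = NULL,
                             missing_rate = 0.02,
                             seed = 20200901,
                             schema = item_schema()) {
  k <- nrow(profiles)
  if (is.null(country_fingerprints))
    country_fingerprints <- list(SYN = rep(1 / k, k))
  if (is.null(n_per_country))
    n_per_country <- stats::setNames(rep(500L * k, length(country_fingerprints)),
                                     names(country_fingerprints))
  stopifnot(missing_rate >= 0, missing_rate < 1,
            length(seed) == 1L, is.finite(seed))
  for (cc in names(country_fingerprints)) {
    w <- country_fingerprints[[cc]]
    if (length(w) != k || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop("mixing proportions for ", cc,
           " must be length ", k, ", non-negative, and sum to 1")
  }
  if (!setequal(names(n_per_country), names(country_fingerprints)))
    stop("n_per_country and country_fingerprints must name the same countries")
  structure(list(profiles = profiles,
                 country_fingerprints = country_fingerprints,
                 n_per_country = n_per_country,
                 missing_rate = missing_rate,
                 seed = as.integer(seed),
                 schema = schema),
            class = "generator_config")
}

# Matched latent parameters for every item of every profile (5 main items
# plus the shared minor-item distribution).
profile_item_params <- function(profiles, schema) {
  main_cols <- paste0(schema$main_items, "_mean")
  lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, ]
    main <- lapply(schema$main_items, function(it)
      match_discrete_params(row[[paste0(it, "_mean")]],
                            row[[paste0(it, "_sd")]]))
    minor_mean <- mean(unlist(row[main_cols])) - row$discrimination_mean
    minor <- match_discrete_params(minor_mean, row$discrimination_sd)
    list(main = main, minor = minor)
  })
}

#' Sample a synthetic questionnaire population
#'
#' @param config A [generator_config()].
#' @return List with `matrix` (a [response_matrix()]) and `truth`, a data
#'   frame of the true type label of every respondent (for evaluation only).
#' @examples
#' cfg <- generator_config(n_per_country = c(SYN = 80), missing_rate = 0)
#' pop <- sample_questionnaires(cfg)
#' table(pop$truth$type)
#' @export
sample_questionnaires <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  schema <- config$schema
  params <- profile_item_params(config$profiles, schema)
  k <- nrow(config$profiles)
  codes <- names(config$country_fingerprints)
  country <- rep(codes, times = config$n_per_country[codes])
  n <- length(country)
  type <- integer(n)
  for (cc in codes) {
    idx <- which(country == cc)
    type[idx] <- sample.int(k, length(idx), replace = TRUE,
                            prob = config$country_fingerprints[[cc]])
  }
  items <- matrix(NA_real_, n, 8L,
                  dimnames = list(NULL, schema$all_items))
  for (t in seq_len(k)) {
    idx <- which(type == t)
    if (!length(idx)) next
    pp <- params[[t]]
    for (j in seq_along(schema$main_items))
      items[idx, j] <- sample_likert(length(idx), pp$main[[j]]$mu,
                                     pp$main[[j]]$sigma)
    for (j in seq_along(schema$minor_items))
      items[idx, 5L + j] <- sample_likert(length(idx), pp$minor$mu,
                                          pp$minor$sigma)
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * 8L) < config$missing_rate, n, 8L)
    # never blank out a whole questionnaire
    allgone <- rowSums(drop) == 8L
    drop[allgone, 1L] <- FALSE
    items[drop] <- NA_real_
  }
  list(matrix = response_matrix(items, country, schema),
       truth = data.frame(country = country, type = type))
}

#' Sample a country index with a target Spearman correlation
#'
#' Builds one synthetic index value per country by blending the ranks of a
#' fingerprint component with independent noise through a Gaussian copula.
#' The latent Pearson parameter is set to `2 * sin(pi * target_rho / 6)`, the
#' classical correspondence under which the population Spearman correlation
#' of the blend equals `target_rho` exactly; the realised (finite-sample)
#' correlation is reported.
#'
#' @param component Named numeric vector: fingerprint component value per
#'   country (length >= 5, not all equal).
#' @param target_rho Target Spearman correlation in `[-1, 1]`.
#' @param seed Integer RNG seed.
#' @return List with `index` (named numeric vector) and `realised_rho`.
#' @export
sample_index <- function(component, target_rho, seed = 1L) {
  n <- length(component)
  stopifnot(n >= 5L, target_rho >= -1, target_rho <= 1)
  if (length(unique(component)) == 1L)
    stop("degenerate component: all countries have the same value")
  set.seed(as.integer(seed))
  z <- stats::qnorm((rank(component, ties.method = "average") - 0.5) / n)
  rp <- 2 * sin(pi * target_rho / 6)
  y <- rp * z + sqrt(max(0, 1 - rp^2)) * stats::rnorm(n)
  index <- stats::setNames(y, names(component))
  list(index = index,
       realised_rho = spearman(component, index)$r)
}
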