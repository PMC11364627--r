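# Direct-summation oracle for the discretised-Gaussian moments.
oracle_moments <- function(mu, sigma) {
  p <- diff(pnorm(c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf), mu, sigma))
  m <- sum(p * (1:5))
  c(mean = m, sd = sqrt(sum(p * (1:5)^2) - m^2))
}

test_that("discrete parameter matching recovers target means on the grid", {
  # symmetric case: mu must equal the target
  sym <- match_discrete_params(3.0, 1.0)
  expect_equal(sym$mu, 3.0, tolerance = 1e-6)

  # printed profile extremes, checked against the summation oracle
  for (tgt in list(c(4.94, 0.24), c(1.33, 0.47), c(4.97, 0.16),
                   c(2.55, 1.18), c(3.20, 0.91))) {
    got <- match_discrete_params(tgt[1], tgt[2])
    om <- oracle_moments(got$mu, got$sigma)
    expect_equal(unname(om["mean"]), tgt[1], tolerance = 0.01)
    expect_equal(got$achieved_mean, unname(om["mean"]), tolerance = 1e-9)
  }
  expect_error(match_discrete_params(0.5, 1), "target_mean")
})

test_that("sampled questionnaires honour the configured mixture", {
  cfg <- generator_config(n_per_country = c(SYN = 300), missing_rate = 0,
                          seed = 7)
  pop <- sample_questionnaires(cfg)
  expect_false(anyNA(pop$matrix$items))
  expect_true(all(pop$matrix$items %in% 1:5))
  expect_identical(nrow(pop$matrix$items), 300L)

  # determinism under a fixed seed
  pop2 <- sample_questionnaires(cfg)
  expect_identical(pop$matrix$items, pop2$matrix$items)
  expect_identical(pop$truth, pop2$truth)

  # pure type-6 country: habitat-loss mean close to the generating 4.97
  cfg6 <- generator_config(
    country_fingerprints = list(ONE = c(0, 0, 0, 0, 0, 1, 0, 0)),
    n_per_country = c(ONE = 400), missing_rate = 0, seed = 11)
  pop6 <- sample_questionnaires(cfg6)
  expect_equal(mean(pop6$matrix$items[, "habitat_loss"]), 4.97,
               tolerance = 0.1)
  expect_true(all(pop6$truth$type == 6))
})

test_that("mixing proportions and missingness converge to configuration", {
  w <- c(0.5, 0.2, 0, 0, 0, 0.1, 0.1, 0.1)
  n <- 2000L
  cfg <- generator_config(country_fingerprints = list(MIX = w),
                          n_per_country = c(MIX = n),
                          missing_rate = 0.05, seed = 3)
  pop <- sample_questionnaires(cfg)
  freq <- tabulate(pop$truth$type, 8) / n
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(freq - w) <= 3 * pmax(se, 1e-3)))
  miss <- mean(is.na(pop$matrix$items))
  se_m <- sqrt(0.05 * 0.95 / (n * 8))
  expect_lt(abs(miss - 0.05), 3 * se_m + 1 / (n * 8))
})

test_that("synthetic indices hit the target rank correlation", {
  comp <- setNames(runif(37), paste0("C", 1:37))
  up <- sample_index(comp, 1, seed = 5)
  expect_equal(up$realised_rho, 1)
  down <- sample_index(comp, -1, seed = 5)
  expect_equal(down$realised_rho, -1)
  expect_error(sample_index(setNames(rep(0.2, 10), paste0("C", 1:10)), 0.5),
               "degenerate")

  # Monte-Carlo over seeds: mean realised rho near the 0.5 target
  rhos <- vapply(1:200, function(s)
    sample_index(comp, 0.5, seed = s)$realised_rho, numeric(1))
  expect_equal(mean(rhos), 0.5, tolerance = 0.1)
})

test_that("printed-profile mixtures overlap: even the true-model classifier errs", {
  # Items are drawn independently within a type at the printed SDs, so the
  # type clouds overlap; classify by exact posterior under the generating
  # model to measure the separation ceiling any clustering method faces.
  cfg <- generator_config(n_per_country = c(SYN = 2000), missing_rate = 0,
                          seed = 303)
  pop <- sample_questionnaires(cfg)
  tab2 <- load_fixture("table2")
  sch <- item_schema()
  masses <- lapply(seq_len(nrow(tab2)), function(t) {
    row <- tab2[t, ]
    mm <- sapply(sch$main_items, function(it) {
      p <- match_discrete_params(row[[paste0(it, "_mean")]],
                                 row[[paste0(it, "_sd")]])
      diff(pnorm(c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf), p$mu, p$sigma))
    })
    minor_mean <- mean(unlist(row[paste0(sch$main_items, "_mean")])) -
      row$discrimination_mean
    p <- match_discrete_params(minor_mean, row$discrimination_sd)
    cbind(mm, replicate(3, diff(pnorm(c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf),
                                      p$mu, p$sigma))))
  })
  X <- pop$matrix$items
  ll <- sapply(masses, function(M)
    rowSums(matrix(log(M[cbind(as.vector(X), rep(1:8, each = nrow(X)))]),
                   nrow(X), 8)))
  acc <- mean(max.col(ll) == pop$truth$type)
  # the Bayes ceiling sits near 88%: well above chance, well below the
  # near-perfect assignment that tight, separated types would allow
  expect_gt(acc, 0.8)
  expect_lt(acc, 0.95)
})
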