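test_that("ward_cluster handles the trivial and separable cases", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40)
  expect_true(all(ward_cluster(x, 1) == 1))
  expect_identical(sort(unique(as.integer(ward_cluster(x, 40)))), 1:40)
  expect_error(ward_cluster(x, 41), "1..n")
  expect_error(ward_cluster(rbind(x, Inf), 2), "non-finite")

  pts <- cbind(c(0, 1, 10, 11), 0, 0, 0, 0, 0)
  lab <- ward_cluster(pts, 2)
  expect_identical(lab[1], lab[2])
  expect_identical(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
  # merge heights non-decreasing
  expect_true(all(diff(attr(lab, "tree")$height) >= -1e-12))
})

test_that("ward_cluster agrees with exhaustive agglomeration on small sets", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:7, 1)
    x <- matrix(rnorm(n * 3), n)
    oracle <- brute_ward(x)
    lab_all <- ward_cluster(x, 1)
    hc <- attr(lab_all, "tree")
    for (k in 1:n) {
      got <- cutree(hc, k)
      want <- partition_labels(oracle$partitions[[k]], n)
      expect_true(same_partition(got, want),
                  label = sprintf("seed %d, k %d partitions agree", seed, k))
    }
    # heights encode the merge cost: height = sqrt(2 * delta-SSE)
    expect_equal(hc$height, sqrt(2 * oracle$deltas), tolerance = 1e-8)
  }
})

test_that("within-cluster dispersion matches direct summation", {
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(within_dispersion(x, 1:6), 0)
  two <- x[1:2, ]
  d <- sqrt(sum((two[1, ] - two[2, ])^2))
  expect_equal(within_dispersion(two, c(1, 1)), d^2 / 2)
  labs <- c(1, 1, 2, 2, 2, 1)
  expect_equal(within_dispersion(x, labs),
               brute_sse(x, split(1:6, labs)))
  expect_error(within_dispersion(x, c(1, 1, NA, 2, 2, 1)), "label")
})

test_that("gap statistic recovers no structure and clear structure", {
  # one spherical blob: k = 1 selected in >= 90% of seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(200 * 6), 200)
    g <- gap_statistic(x, 1:6, B = 50, seed = s)
    hits <- hits + (g$selected_k == 1L)
  }
  expect_gte(hits, 18L)

  # two well-separated blobs
  set.seed(33)
  x2 <- rbind(matrix(rnorm(100 * 6), 100),
              matrix(rnorm(100 * 6, mean = 10), 100))
  g2 <- gap_statistic(x2, 1:6, B = 50, seed = 1)
  expect_identical(g2$selected_k, 2L)

  expect_error(gap_statistic(x2, integer(0)), "empty")
  expect_error(gap_statistic(cbind(1:10, 1), 1:3, B = 10), "zero-range")
})

test_that("profiles summarise clusters on un-jittered features", {
  sch <- item_schema()
  x <- rbind(matrix(rep(c(5, 5, 5, 5, 5, 4), 4), 4, byrow = TRUE),
             matrix(rep(c(2, 2, 2, 2, 2, -1), 3), 3, byrow = TRUE))
  colnames(x) <- c(sch$main_items, "discrimination")
  prof <- extract_profiles(x, c(1, 1, 1, 1, 2, 2, 2), sch)
  expect_identical(nrow(prof), 2L)
  expect_identical(sum(prof$size), 7L)
  # identical rows give SD 0; ordering is by descending discrimination
  expect_equal(prof$climate_change_sd, c(0, 0))
  expect_equal(prof$discrimination_mean, c(4, -1))
  expect_equal(prof$climate_change_mean, c(5, 2))

  # two-cluster toy: means equal hand-computed column means
  set.seed(2)
  y <- matrix(runif(10 * 6, 1, 5), 10,
              dimnames = list(NULL, c(sch$main_items, "discrimination")))
  labs <- rep(1:2, each = 5)
  p2 <- extract_profiles(y, labs, sch)
  relab <- attr(p2, "relabel")
  for (g in 1:2) {
    row <- p2[p2$type_id == relab[[as.character(g)]], ]
    expect_equal(row$pollution_mean, mean(y[labs == g, "pollution"]))
    expect_equal(row$discrimination_sd, sd(y[labs == g, "discrimination"]))
  }
  # relabelling clusters changes no profile content
  p3 <- extract_profiles(y, 3 - labs, sch)
  expect_equal(p2[, -1], p3[, -1], ignore_attr = TRUE)
})

test_that("profile matching finds the optimal assignment", {
  ref <- load_fixture("table2")
  # identical profiles: identity mapping at distance 0
  m0 <- match_profiles(ref, ref)
  expect_identical(m0$reference_id, ref$type_id)
  expect_equal(m0$distance, rep(0, 8))

  # swapped reference rows: the swap is recovered
  swapped <- ref[c(2, 1, 3:8), ]
  swapped$type_id <- 1:8
  m1 <- match_profiles(swapped, ref)
  expect_identical(m1$reference_id, c(2L, 1L, 3:8))

  # small perturbation: identity mapping, checked against all 8! assignments
  pert <- ref
  cols <- c(paste0(item_schema()$main_items, "_mean"), "discrimination_mean")
  pert[, cols] <- pert[, cols] + 0.05
  m2 <- match_profiles(pert, ref)
  expect_identical(m2$reference_id, ref$type_id)
  cost <- as.matrix(dist(rbind(as.matrix(pert[, cols]),
                               as.matrix(ref[, cols]))))[1:8, 9:16]
  perms <- resptyper:::permutations_of(8)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(1:8, p)]))
  expect_equal(sum(m2$distance), min(totals))

  expect_error(match_profiles(ref[1:3, ], ref), "count")
})
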