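test_that("circular gaps conserve the full angle and handle symmetry", {
  expect_equal(sort(circular_gaps(c(0, pi))), c(pi, pi))
  n <- 8
  expect_equal(circular_gaps(2 * pi * (0:(n - 1)) / n), rep(2 * pi / n, n))
  set.seed(2)
  for (i in 1:20) {
    th <- runif(sample(2:15, 1), 0, 2 * pi)
    expect_equal(sum(circular_gaps(th)), 2 * pi, tolerance = 1e-9)
  }
  expect_error(circular_gaps(1.0), "at least 2")
})

test_that("gap clustering cuts exactly at large gaps", {
  # no gap above g: a single sector
  th <- seq(0, 1, length.out = 10)
  coords <- data.frame(node = paste0("n", 1:10), theta = th)
  p1 <- suppressWarnings(angular_gap_clusters(coords, g = 0.5, min_size = 1))
  expect_equal(nrow(p1$sectors), 1)
  expect_equal(unique(p1$assignments$sector_id), 1L)
  # two tight blocks
  coords <- data.frame(node = paste0("n", 1:6),
                       theta = c(0.00, 0.01, 0.02, 1.00, 1.01, 1.02))
  p2 <- suppressWarnings(angular_gap_clusters(coords, g = 0.5, min_size = 1))
  expect_equal(nrow(p2$sectors), 2)
  expect_equal(sort(p2$sectors$size), c(3L, 3L))
  sets <- partition_sets(p2$assignments$node, p2$assignments$sector_id)
  expect_identical(sets, list(c("n1", "n2", "n3"), c("n4", "n5", "n6")))
})

test_that("gap clustering equals the brute-force circular oracle", {
  set.seed(31)
  for (case in 1:200) {
    n <- sample(3:12, 1)
    th <- runif(n, 0, 2 * pi)
    g <- runif(1, 0.05, 2)
    coords <- data.frame(node = sprintf("x%02d", seq_len(n)), theta = th)
    got <- suppressWarnings(angular_gap_clusters(coords, g = g, min_size = 1))
    oracle <- oracle_gap_partition(th, g)
    expect_identical(
      partition_sets(got$assignments$node, got$assignments$sector_id),
      partition_sets(coords$node, oracle))
    # partition property: disjoint cover
    expect_setequal(got$assignments$node, coords$node)
    expect_equal(sum(got$sectors$size), n)
  }
})

test_that("sector count is non-increasing in the gap threshold", {
  set.seed(17)
  th <- runif(60, 0, 2 * pi)
  coords <- data.frame(node = paste0("n", 1:60), theta = th)
  counts <- vapply(seq(0.01, 1.2, length.out = 25), function(g) {
    nrow(suppressWarnings(
      angular_gap_clusters(coords, g = g, min_size = 1))$sectors)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical angles always share a sector", {
  coords <- data.frame(node = c("b", "a", "c", "d"),
                       theta = c(1, 1, 1, 4))
  p <- suppressWarnings(angular_gap_clusters(coords, g = 0.5, min_size = 1))
  ids <- p$assignments$sector_id[p$assignments$node %in% c("a", "b", "c")]
  expect_equal(length(unique(ids)), 1)
})

test_that("merge policy absorbs undersized sectors across the smaller gap", {
  # three blocks: sizes 5, 2, 5; the small block is nearer the first block
  th <- c(seq(0.00, 0.08, length.out = 5),  # block A ends at 0.08
          c(0.30, 0.32),                    # small block, gap 0.22 to A
          seq(1.00, 1.08, length.out = 5))  # block B, gap 0.68 from small
  coords <- data.frame(node = sprintf("n%02d", seq_along(th)), theta = th)
  kept <- suppressWarnings(
    angular_gap_clusters(coords, g = 0.15, min_size = 5, policy = "keep"))
  expect_equal(nrow(kept$sectors), 3)
  expect_warning(
    angular_gap_clusters(coords, g = 0.15, min_size = 5, policy = "keep"),
    "smaller than min_size")
  merged <- angular_gap_clusters(coords, g = 0.15, min_size = 5,
                                 policy = "merge")
  expect_equal(nrow(merged$sectors), 2)
  a <- merged$assignments
  expect_equal(unique(a$sector_id[a$node %in% c("n06", "n07")]),
               unique(a$sector_id[a$node == "n01"]))
  expect_error(angular_gap_clusters(coords, g = 0.15, policy = "nope"))
})

test_that("gap-threshold tuning maximizes sectors under the size floor", {
  # two tight blocks of 5: tuned g separates them into exactly 2 sectors
  th <- c(seq(0, 0.04, length.out = 5), seq(3, 3.04, length.out = 5))
  coords <- data.frame(node = paste0("n", 1:10), theta = th)
  g <- tune_gap_threshold(coords, min_size = 5)
  part <- suppressWarnings(angular_gap_clusters(coords, g = g, min_size = 5))
  expect_equal(nrow(part$sectors), 2)
  expect_true(all(part$sectors$size >= 5))
  expect_lt(g, 3 - 0.04) # below the separating gaps
  # min_size = n: returns the largest observed gap, one sector
  g1 <- tune_gap_threshold(coords, min_size = 10)
  expect_equal(g1, max(circular_gaps(th)))
  expect_equal(nrow(suppressWarnings(
    angular_gap_clusters(coords, g = g1, min_size = 10))$sectors), 1)
  # uniform angles with min_size 1: every node its own sector
  thu <- 2 * pi * (0:7) / 8
  cu <- data.frame(node = paste0("u", 1:8), theta = thu)
  gu <- tune_gap_threshold(cu, min_size = 1)
  expect_equal(nrow(suppressWarnings(
    angular_gap_clusters(cu, g = gu, min_size = 1))$sectors), 8)
  # an angular straggler flanked by the two largest gaps: under "keep" no
  # multi-sector cut is valid, under "merge" the straggler is absorbed
  ths <- c(seq(0, 0.04, length.out = 5), seq(0.5, 0.54, length.out = 5), 3.0)
  cs <- data.frame(node = paste0("s", 1:11), theta = ths)
  g_keep <- tune_gap_threshold(cs, min_size = 5, policy = "keep")
  expect_equal(nrow(suppressWarnings(
    angular_gap_clusters(cs, g = g_keep, min_size = 5))$sectors), 1)
  g_merge <- tune_gap_threshold(cs, min_size = 5, policy = "merge")
  pm <- angular_gap_clusters(cs, g = g_merge, min_size = 5, policy = "merge")
  expect_gte(nrow(pm$sectors), 2)
  expect_true(all(pm$sectors$size >= 5))
  # exhaustive-scan oracle on random instances: no threshold beats the tuned one
  set.seed(41)
  for (case in 1:25) {
    n <- sample(6:14, 1)
    thr <- runif(n, 0, 2 * pi)
    cr <- data.frame(node = paste0("r", seq_len(n)), theta = thr)
    ms <- sample(1:3, 1)
    gt <- tune_gap_threshold(cr, min_size = ms)
    n_at <- function(g) {
      p <- suppressWarnings(angular_gap_clusters(cr, g = g, min_size = ms))
      if (all(p$sectors$size >= ms)) nrow(p$sectors) else NA_integer_
    }
    tuned_k <- n_at(gt)
    expect_false(is.na(tuned_k))
    grid <- sort(unique(c(circular_gaps(thr) * 0.999,
                          circular_gaps(thr) * 1.001)))
    best <- max(c(vapply(grid, n_at, numeric(1)), 1), na.rm = TRUE)
    expect_equal(tuned_k, best)
  }
})
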