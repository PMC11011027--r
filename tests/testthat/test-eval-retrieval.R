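# Retrieval metrics against brute-force oracles, plus ranking invariants.

test_that("euclidean distance matches the loop-sum-sqrt oracle", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(51)
  a <- rnorm(64); b <- rnorm(64)
  s <- 0
  for (j in 1:64) s <- s + (a[j] - b[j])^2
  expect_equal(euclidean_distance(a, b), sqrt(s), tolerance = 1e-9)
  expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  expect_error(euclidean_distance(a, b[1:10]), "lengths differ")
})

test_that("match indicator is the identity-equality function", {
  expect_identical(match_indicator(7, 7), 1L)
  expect_identical(match_indicator(7, 9), 0L)
  set.seed(52)
  ids <- sample.int(1e6, 100)
  expect_true(all(vapply(ids, function(i) match_indicator(i, i), integer(1)) == 1L))
})

test_that("gallery ranking excludes self, sorts ascending, breaks ties stably", {
  desc <- rbind(q = c(0, 0), a = c(3, 4), b = c(0.1, 0), c = c(2, 0))
  g <- gallery_set(desc, labels = c(1, 2, 1, 2), image_ids = c("q", "a", "b", "c"))
  r <- rank_gallery(c(0, 0), "q", g, query_label = 1)
  expect_identical(r$order, c(3L, 4L, 2L))        # distances 0.1, 2, 5
  expect_equal(r$distances, c(0.1, 2, 5))
  expect_false("q" %in% g$image_ids[r$order])
  # exact duplicate under a different id ranks first at distance zero
  g2 <- gallery_set(rbind(c(5, 5), c(0, 0)), labels = c(2, 1), image_ids = c("x", "dup"))
  r2 <- rank_gallery(c(0, 0), "q", g2)
  expect_identical(g2$image_ids[r2$order[1]], "dup")
  expect_equal(r2$distances[1], 0)
  # gallery reduced to the query's own image is an error
  g3 <- gallery_set(matrix(0, 1, 2), labels = 1, image_ids = "q")
  expect_error(rank_gallery(c(0, 0), "q", g3), "empty")
  # ties break by gallery index
  g4 <- gallery_set(rbind(c(1, 0), c(1, 0), c(1, 0)), labels = 1:3)
  r4 <- rank_gallery(c(0, 0), 99, g4)
  expect_identical(r4$order, 1:3)
  expect_error(gallery_set(matrix(0, 2, 2), 1:2, c("a", "a")), "unique")
})

test_that("CMC counts first-hit ranks and is monotone in k", {
  mk <- function(first_hit, n = 10) {
    labs <- rep(0, n); labs[first_hit] <- 1
    structure(list(labels = labs, query_label = 1), class = "ranking_result")
  }
  rks <- list(mk(1), mk(2), mk(6))
  expect_equal(cmc_at_k(rks, 1), 1 / 3)
  expect_equal(cmc_at_k(rks, 5), 2 / 3)
  expect_equal(cmc_at_k(rks, 10), 1)
  curve <- vapply(1:10, function(k) cmc_at_k(rks, k), numeric(1))
  expect_true(all(diff(curve) >= 0))
  # k beyond the gallery size with a guaranteed match saturates at 1
  expect_equal(cmc_at_k(rks, 50), 1)
})

test_that("average precision follows the precision-at-rank arithmetic", {
  r <- structure(list(labels = c(1, 0, 1, 0), query_label = 1),
                 class = "ranking_result")
  expect_equal(as.numeric(mean_average_precision(list(r))),
               (1 / 1 + 2 / 3) / 2, tolerance = 1e-12)
  r2 <- structure(list(labels = c(1, 1, 0), query_label = 1),
                  class = "ranking_result")
  expect_equal(as.numeric(mean_average_precision(list(r2))), 1)
  # a query with no relevant item is excluded with a warning
  r3 <- structure(list(labels = c(0, 0), query_label = 1),
                  class = "ranking_result")
  expect_warning(m <- mean_average_precision(list(r, r3)), "no relevant")
  expect_equal(attr(m, "n_excluded"), 1L)
})

test_that("mAP and CMC agree with the exhaustive oracle on random instances", {
  set.seed(53)
  for (rep in 1:3) {
    n <- sample(12:20, 1)
    desc <- matrix(rnorm(n * 5), n, 5)
    labels <- sample(1:4, n, replace = TRUE)
    # guarantee every query has at least one relevant item
    labels[1:8] <- rep(1:4, 2)
    ev <- evaluate_reid(NULL, list(descriptors = desc, labels = labels))
    oracle <- naive_cmc_map(desc, labels, k_max = n - 1)
    expect_equal(ev$cmc, oracle$cmc, tolerance = 1e-9)
    expect_equal(ev$mAP, oracle$map, tolerance = 1e-9)
    expect_true(all(diff(ev$cmc) >= -1e-12))
  }
})

test_that("rankings and metrics are invariant to positive descriptor scaling", {
  set.seed(54)
  desc <- matrix(rnorm(16 * 6), 16, 6)
  labels <- rep(1:4, each = 4)
  e1 <- evaluate_reid(NULL, list(descriptors = desc, labels = labels))
  e2 <- evaluate_reid(NULL, list(descriptors = 37.5 * desc, labels = labels))
  expect_equal(e1$cmc, e2$cmc)
  expect_equal(e1$mAP, e2$mAP)
})

test_that("a perfectly separable pixel embedder scores mAP 1 and chance stays at 1/2", {
  # per-identity unique constant images, descriptor = raw pixels
  imgs <- lapply(1:10, function(i) array(i / 10, c(4, 8, 3)))
  desc <- t(vapply(imgs, as.vector, numeric(4 * 8 * 3)))
  desc <- desc[rep(1:10, each = 2), ] + 0          # two copies per identity
  labels <- rep(1:10, each = 2)
  ev <- evaluate_reid(NULL, list(descriptors = desc, labels = labels))
  expect_equal(ev$mAP, 1)
  expect_equal(ev$rank1, 1)
  # random descriptors, two balanced classes: Rank-1 near 1/2
  set.seed(55)
  n <- 400
  rd <- matrix(rnorm(n * 8), n, 8)
  rl <- rep(1:2, each = n / 2)
  evr <- evaluate_reid(NULL, list(descriptors = rd, labels = rl))
  p <- (n / 2 - 1) / (n - 1)
  expect_lt(abs(evr$rank1 - p), 3 * sqrt(p * (1 - p) / n))
})
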