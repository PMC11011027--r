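# Local branch: block partition, channel reduction, dual-domain gates and
# the concatenated local descriptor.

test_that("block split partitions the width exactly and reversibly", {
  set.seed(21)
  x <- rand_map(8, 16, 5, 2)
  blocks <- split_blocks(x, 4)
  expect_length(blocks, 4)
  for (b in blocks) expect_identical(dim(b), c(8L, 4L, 5L, 2L))
  rebuilt <- array(0, dim(x))
  for (i in 1:4) rebuilt[, (i - 1) * 4 + 1:4, , ] <- blocks[[i]]
  expect_identical(rebuilt, x)                 # bit-for-bit reconstruction
  expect_identical(split_blocks(x, 1)[[1]], x) # identity partition
  expect_error(split_blocks(rand_map(8, 15, 5), 4), "not divisible")
})

test_that("block reduction max-pools then projects to the local width", {
  laem <- with_seed_test(22, new_laem(32, c_red = 16))
  set.seed(23)
  blk <- rand_map(2, 2, 32, 2)
  red <- reduce_block(laem, blk)
  expect_identical(dim(red), c(1L, 1L, 16L, 2L))
  # pooled values equal the per-channel max computed by explicit loop
  unit <- laem$units[[1]]
  pooled <- tr$global_max_pool(blk)$out
  for (b in 1:2) for (ch in 1:32) {
    m <- -Inf
    for (i in 1:2) for (j in 1:2) m <- max(m, blk[i, j, ch, b])
    expect_equal(pooled[b, ch], m)
  }
  # a single-peak block pools to that peak before the projection
  one <- array(0, c(3, 3, 32, 1)); one[2, 3, , 1] <- 5
  expect_equal(tr$global_max_pool(one)$out, matrix(5, 1, 32))
  expect_error(reduce_block(laem, rand_map(2, 2, 8, 1)), "channels")
})

test_that("channel gate equals the closed-form MLP evaluation and stays in (0,1)", {
  unit <- with_seed_test(24, new_attention_unit(4, reduction = 2, kernel = 1))
  set.seed(25)
  x <- rand_map(2, 2, 4, 2)
  g <- channel_attention(x, unit = unit)
  expect_true(all(g > 0 & g < 1))
  # closed-form oracle with the pinned weights
  for (b in 1:2) {
    avg <- vapply(1:4, function(c) mean(x[, , c, b]), numeric(1))
    mx <- vapply(1:4, function(c) max(x[, , c, b]), numeric(1))
    mlp <- function(v) {
      h <- pmax(as.vector(v %*% unit$ca_fc1$W + unit$ca_fc1$b), 0)
      as.vector(h %*% unit$ca_fc2$W + unit$ca_fc2$b)
    }
    expect_equal(as.vector(g[b, ]), 1 / (1 + exp(-(mlp(avg) + mlp(mx)))),
                 tolerance = 1e-12)
  }
  # zero weights -> sigmoid(0) = 0.5 everywhere
  zero_attention_unit(unit)
  expect_equal(as.vector(channel_attention(x, unit = unit)), rep(0.5, 8))
  expect_error(new_attention_unit(4, reduction = 8), "not divisible")
})

test_that("spatial gate matches hand evaluation with a pinned 1x1 kernel", {
  unit <- with_seed_test(26, new_attention_unit(3, reduction = 1, kernel = 1))
  set.seed(27)
  x <- rand_map(3, 3, 3, 1)
  g <- spatial_attention(x, kernel = 1, unit = unit)
  expect_identical(dim(g), c(3L, 3L, 1L, 1L))
  w_mean <- unit$sa$W[1, 1, 1, 1]; w_max <- unit$sa$W[1, 1, 2, 1]
  for (i in 1:3) for (j in 1:3) {
    m <- mean(x[i, j, , 1]); mx <- max(x[i, j, , 1])
    expect_equal(g[i, j, 1, 1],
                 1 / (1 + exp(-(w_mean * m + w_max * mx + unit$sa$b))),
                 tolerance = 1e-12)
  }
  # zero weights -> uniform 0.5; 1x1 input degenerates to one scalar gate
  zero_attention_unit(unit)
  expect_equal(as.vector(spatial_attention(x, kernel = 1, unit = unit)),
               rep(0.5, 9))
  g1 <- spatial_attention(rand_map(1, 1, 3), kernel = 7,
                          unit = with_seed_test(28, new_attention_unit(3, 1, 7)))
  expect_identical(dim(g1), c(1L, 1L, 1L, 1L))
  expect_error(spatial_attention(x, kernel = 4), "odd")
})

test_that("dual-domain gating composes the two gates and never amplifies", {
  unit <- with_seed_test(29, new_attention_unit(4, reduction = 2, kernel = 3))
  set.seed(30)
  x <- rand_map(2, 2, 4, 2)
  y <- cbam(x, unit = unit)
  expect_true(all(abs(y) <= abs(x) + 1e-15))
  # composed oracle: channel gate applied first, spatial gate on the gated map
  gc <- channel_attention(x, unit = unit)
  xc <- x * tr$expand_channel_gate(gc, dim(x))
  gs <- tr$sa_forward(unit, xc)$gate
  expect_equal(unclass(y), xc * tr$expand_spatial_gate(gs, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero weights throughout: both gates 0.5, so the output is 0.25 x input
  zero_attention_unit(unit)
  expect_equal(unclass(cbam(x, unit = unit)), 0.25 * x, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("local branch emits four 512-scaled part vectors with shared weights", {
  laem <- with_seed_test(31, new_laem(64, c_red = 16))
  set.seed(32)
  fused <- rand_map(4, 8, 64, 2)
  lb <- local_branch(laem, fused)
  expect_length(lb$L, 4)
  for (L in lb$L) {
    expect_identical(dim(L), c(2L, 16L))
    expect_true(all(L >= 0) && all(is.finite(L)))
  }
  expect_identical(dim(lb$f_local), c(2L, 64L))  # 4 x 16 concatenated
  # zero fused map with zero reduction bias -> zero local descriptor
  laem$units[[1]]$reduce$b[] <- 0
  lb0 <- local_branch(laem, fused * 0)
  expect_true(all(lb0$f_local == 0))
  # shared weights: swapping the two middle blocks permutes L2/L3 only
  swapped <- fused
  swapped[, 3:4, , ] <- fused[, 5:6, , ]
  swapped[, 5:6, , ] <- fused[, 3:4, , ]
  lb2 <- local_branch(laem, swapped)
  expect_equal(lb2$L[[1]], lb$L[[1]])
  expect_equal(lb2$L[[4]], lb$L[[4]])
  expect_equal(lb2$L[[2]], lb$L[[3]])
  expect_equal(lb2$L[[3]], lb$L[[2]])
  # locality: perturbing block 2 leaves the other part vectors unchanged
  pert <- fused
  pert[, 3:4, , ] <- pert[, 3:4, , ] + rand_map(4, 2, 64, 2)
  lb3 <- local_branch(laem, pert)
  expect_equal(lb3$L[[1]], lb$L[[1]])
  expect_equal(lb3$L[[3]], lb$L[[3]])
  expect_equal(lb3$L[[4]], lb$L[[4]])
  expect_false(isTRUE(all.equal(lb3$L[[2]], lb$L[[2]])))
})

test_that("post-pooling attention variant preserves the descriptor contract", {
  laem <- with_seed_test(33, new_laem(64, c_red = 16, pool_position = "post"))
  fused <- rand_map(4, 8, 64, 2)
  lb <- local_branch(laem, fused)
  expect_identical(dim(lb$f_local), c(2L, 64L))
  expect_true(all(lb$f_local >= 0))
})
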