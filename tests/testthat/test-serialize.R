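test_that("voxelization uses half-open bins and covers every point", {
  pc <- point_cloud(rbind(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9)))
  g1 <- voxelize(pc, 1.0, origin = c(0, 0, 0))
  expect_equal(nrow(g1$voxel_coords), 1)
  g2 <- voxelize(pc, 0.5, origin = c(0, 0, 0))
  expect_equal(nrow(g2$voxel_coords), 2)
  expect_equal(g2$voxel_coords[g2$point_to_voxel[1], ], c(0L, 0L, 0L),
               ignore_attr = TRUE)
  expect_equal(g2$voxel_coords[g2$point_to_voxel[2], ], c(1L, 1L, 1L),
               ignore_attr = TRUE)
  expect_error(voxelize(pc, 0), "positive")

  set.seed(8)
  pc <- point_cloud(matrix(runif(900, 0, 10), ncol = 3))
  g <- voxelize(pc, 0.7)
  counts <- table(g$point_to_voxel)
  expect_equal(sum(counts), nrow(pc))
  expect_equal(length(g$point_to_voxel), nrow(pc))
})

test_that("Morton encoding matches the single-bit cases and the digit oracle", {
  expect_equal(zorder_encode(rbind(c(0, 0, 0)), 3), 0L)
  expect_equal(zorder_encode(rbind(c(1, 0, 0)), 3), 1L)
  expect_equal(zorder_encode(rbind(c(0, 1, 0)), 3), 2L)
  expect_equal(zorder_encode(rbind(c(0, 0, 1)), 3), 4L)
  expect_equal(zorder_encode(rbind(c(3, 5, 1)), 3), 143L)
  expect_equal(oracle_morton(3, 5, 1, 3), 143)
  expect_error(zorder_encode(rbind(c(8, 0, 0)), 3), "x coordinate")
  expect_error(zorder_encode(rbind(c(0, 0, 9)), 3), "z coordinate")
})

test_that("Morton encoding is injective and matches the oracle exhaustively (b = 3)", {
  grid <- as.matrix(expand.grid(x = 0:7, y = 0:7, z = 0:7))
  z <- zorder_encode(grid, 3)
  expect_equal(length(unique(z)), nrow(grid))
  oracle <- mapply(oracle_morton, grid[, 1], grid[, 2], grid[, 3], 3)
  expect_equal(z, as.integer(oracle))
})

test_that("Z-order of a 4x4x4 grid matches the recursive octant traversal", {
  grid <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3))
  zseq <- zorder_sequence(grid)
  visited <- grid[zseq$perm, ]
  expect_equal(unname(visited), unname(oracle_octant_order(2)))
})

test_that("serialize and restore are inverse permutations", {
  set.seed(10)
  for (rep in 1:20) {
    m <- sample(5:40, 1)
    coords <- unique(matrix(sample(0:7, m * 3, replace = TRUE), ncol = 3))
    feats <- matrix(rnorm(nrow(coords) * 4), ncol = 4)
    zseq <- zorder_sequence(coords)
    expect_identical(restore(serialize(feats, zseq), zseq), feats)
  }
  # already-sorted input keeps identity order
  grid <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  ord <- order(zorder_encode(grid, 1))
  zseq <- zorder_sequence(grid[ord, ])
  expect_equal(zseq$perm, 1:8)
  expect_error(serialize(matrix(0, 3, 1), zseq), "match")
})

test_that("softplus is positive with the closed-form value at zero", {
  expect_equal(treeparse3d:::softplus(0), log(2), tolerance = 1e-12)
  set.seed(12)
  x <- rnorm(1e4, 0, 10)
  expect_true(all(treeparse3d:::softplus(x) > 0))
  expect_equal(treeparse3d:::softplus(50), 50, tolerance = 1e-9)
})

test_that("the sequential scan matches a hand-unrolled 3-step recurrence", {
  set.seed(13)
  blk <- ssm_block(1, n_state = 1, seed = 13)
  u <- matrix(rnorm(3), 3, 1)
  y <- selective_scan(u, blk, "sequential")
  dt <- treeparse3d:::softplus(as.numeric(u %*% t(blk$W_dt)) + blk$b_dt)
  Bv <- as.numeric(u %*% t(blk$W_B))
  Cv <- as.numeric(u %*% t(blk$W_C))
  y_oracle <- oracle_scan3(as.numeric(u), dt, Bv, Cv, blk$A[1, 1], blk$D)
  expect_lt(max(abs(as.numeric(y) - y_oracle)), 1e-9)
})

test_that("sequential and parallel scans agree in the A = 0 limit and diverge for general A", {
  set.seed(14)
  blk <- ssm_block(4, n_state = 3, seed = 14)
  u <- matrix(rnorm(40), 10, 4)
  blk0 <- blk; blk0$A[] <- 0
  y_seq <- selective_scan(u, blk0, "sequential")
  y_par <- selective_scan(u, blk0, "parallel")
  expect_lt(max(abs(y_seq - y_par)), 1e-6)
  # shrinking ||A|| shrinks the divergence
  divergence <- vapply(c(1, 0.1, 0.01), function(s) {
    bs <- blk; bs$A <- blk$A * s
    max(abs(selective_scan(u, bs, "sequential") - selective_scan(u, bs, "parallel")))
  }, 0)
  expect_true(all(diff(divergence) < 0))
  expect_gt(divergence[1], 1e-6)  # the two forms are not identical in general
})

test_that("rmsnorm normalizes row RMS to 1 and is scale invariant at eps = 0", {
  expect_equal(rmsnorm(c(1, 1, 1, 1), w = 1, eps = 0), c(1, 1, 1, 1))
  expect_equal(rmsnorm(c(3, 4), w = 1, eps = 0), c(0.848528, 1.131371),
               tolerance = 1e-6)
  set.seed(15)
  y <- matrix(rnorm(60), 10, 6)
  out <- rmsnorm(y, w = 1, eps = 0)
  expect_lt(max(abs(sqrt(rowMeans(out^2)) - 1)), 1e-6)
  expect_lt(max(abs(rmsnorm(3.7 * y, eps = 0) - rmsnorm(y, eps = 0))), 1e-6)
})

test_that("voxel-pooled scan round trip preserves the point count", {
  gen <- generate_plantation(plantation_spec(rows = 1, trees_per_row = 2, seed = 2))
  feats <- cbind(gen$pc$z, as.numeric(gen$pc$semantic))
  out <- ssm_encode(gen$pc, feats, voxel_size = 0.5,
                    block = ssm_block(2, n_state = 4, seed = 1))
  expect_equal(nrow(out), nrow(gen$pc))
  expect_true(all(is.finite(out)))
  # members of one voxel share the scattered feature
  grid <- voxelize(gen$pc, 0.5)
  v1 <- which(grid$point_to_voxel == grid$point_to_voxel[1])
  expect_equal(out[v1, , drop = FALSE],
               out[rep(v1[1], length(v1)), , drop = FALSE])
})
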