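params_small <- encoder_params(d_s = 8, d_feat = 8, n_branch = 3, K = 4,
                               d_out = 4, seed = 11)

square_ann <- function(shift = 0, ids = 1:2) {
  crown_annotation_set(tibble::tibble(
    instance_id = ids, label = rep("crown", 2),
    polygon = list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)) + shift,
                   cbind(c(5, 8, 8, 5), c(0, 0, 3, 3)) + shift)))
}

test_that("annotation encoding is deterministic, order-invariant, zero on empty sets", {
  ann <- square_ann()
  f1 <- encode_json(ann, params_small)
  f2 <- encode_json(ann, params_small)
  expect_identical(f1, f2)
  expect_length(f1, params_small$d_s)

  # permuting polygon order leaves the semantic vector unchanged
  ann_perm <- crown_annotation_set(ann$polygons[2:1, ])
  expect_equal(encode_json(ann_perm, params_small), f1, tolerance = 1e-12)

  empty <- crown_annotation_set()
  expect_identical(treeparse3d:::annotation_descriptor(empty), rep(0, 12))
  expect_equal(encode_json(empty, params_small), rep(0, params_small$d_s))
})

test_that("template has the 8 x D shape, is zero under zero weights, and responds to F_s", {
  f_s <- rnorm(params_small$d_s)
  H <- build_template(f_s, params_small)
  expect_equal(dim(H), c(8L, params_small$d_feat))

  p0 <- params_small
  p0$mlp_hypercube$W2[] <- 0
  expect_true(all(build_template(f_s, p0) == 0))

  # finite-difference gradient of one entry w.r.t. one input is nonzero
  h <- 1e-5
  for (j in c(1, 5)) {
    fp <- f_s; fp[j] <- fp[j] + h
    fm <- f_s; fm[j] <- fm[j] - h
    grad <- (build_template(fp, params_small)[1, 1] -
               build_template(fm, params_small)[1, 1]) / (2 * h)
    expect_gt(abs(grad), 1e-8)
  }
})

test_that("trilinear weights hit the corner one-hot and center cases exactly", {
  W <- trilinear_weights(rbind(c(0, 0, 0), c(1, 1, 1), c(0.5, 0.5, 0.5)))
  expect_equal(W[1, ], c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(W[2, ], c(0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(W[3, ], rep(1 / 8, 8))
  # the remaining six corners are one-hot at the matching vertex
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  Wc <- trilinear_weights(corners)
  expect_equal(Wc, diag(8), ignore_attr = TRUE)
  expect_error(trilinear_weights(rbind(c(NaN, 0, 0))), "NaN")
  expect_warning(trilinear_weights(rbind(c(-0.2, 0.5, 0.5))), "clamped")
})

test_that("trilinear rows sum to one and fusion matches the dense product", {
  set.seed(2)
  coords <- matrix(runif(3000), ncol = 3)
  W <- trilinear_weights(coords)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-6)
  expect_true(all(W >= 0 & W <= 1))

  H <- matrix(rnorm(8 * 6), 8, 6)
  F1 <- fuse(H, W)
  oracle <- matrix(0, nrow(W), 6)
  for (n in 1:nrow(W)) for (d in 1:6) {
    oracle[n, d] <- sum(W[n, ] * H[, d])
  }
  expect_lt(max(abs(F1 - oracle)), 1e-6)

  # linearity in the template
  H2 <- matrix(rnorm(8 * 6), 8, 6)
  expect_lt(max(abs(fuse(H + H2, W) - (fuse(H, W) + fuse(H2, W)))), 1e-6)

  # a corner point reproduces its template vertex; the center the vertex mean
  Wc <- trilinear_weights(rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)))
  Fc <- fuse(H, Wc)
  expect_equal(Fc[1, ], H[1, ])
  expect_equal(Fc[2, ], colMeans(H))
})

test_that("branch weights are simplex rows with softmax identities", {
  set.seed(3)
  Ff <- matrix(rnorm(50 * params_small$d_feat), 50)
  B <- select_branches(Ff, params_small)
  expect_equal(dim(B), c(50L, 3L))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-6)

  p0 <- params_small
  p0$mlp_b$W2[] <- 0
  expect_equal(select_branches(Ff, p0), matrix(1 / 3, 50, 3), tolerance = 1e-12)

  # shift invariance: adding a constant to all logits changes nothing
  logits <- matrix(rnorm(20 * 3), 20)
  expect_equal(treeparse3d:::softmax_rows(logits),
               treeparse3d:::softmax_rows(logits + 7), tolerance = 1e-12)
})

test_that("sparse gating obeys the strict threshold and is monotone in tau", {
  set.seed(4)
  coords <- matrix(runif(300), ncol = 3)
  f_s <- rnorm(params_small$d_s)

  p0 <- params_small
  p0$mlp_g$W2[] <- 0
  g0 <- sparse_gate(coords, f_s, p0, tau_g = 0.5)
  expect_true(all(g0$g_mask == 0.5))
  expect_length(g0$masked, 0)   # strict inequality retains nothing

  g_all <- sparse_gate(coords, f_s, params_small, tau_g = 1e-9)
  expect_length(g_all$masked, nrow(coords))

  sizes <- vapply(seq(0.05, 0.95, by = 0.09), function(tau) {
    length(sparse_gate(coords, f_s, params_small, tau_g = tau)$masked)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("entanglement matrices are the PSD second moments of the subspace states", {
  f_s <- rnorm(params_small$d_s)
  # N = 1 with a unit state vector in subspace j gives e1 e1^T
  p1 <- params_small
  ent <- entangle(matrix(rnorm(params_small$d_feat), 1),
                  matrix(runif(3), 1), f_s, p1)
  for (j in 1:4) {
    q <- ent$q_states[1, j, ]
    expect_equal(ent$q_entangle[[j]], q %o% q, tolerance = 1e-12)
  }

  # all-zero input states give zero matrices
  p0 <- params_small
  p0$W_q[] <- 0
  ent0 <- entangle(matrix(rnorm(5 * params_small$d_feat), 5),
                   matrix(runif(15), ncol = 3), f_s, p0)
  expect_true(all(vapply(ent0$q_entangle, function(m) all(m == 0), TRUE)))

  # symmetry + PSD for random inputs, and invariance to point order
  set.seed(5)
  Ff <- matrix(rnorm(40 * params_small$d_feat), 40)
  coords <- matrix(runif(120), ncol = 3)
  ent1 <- entangle(Ff, coords, f_s, params_small)
  perm <- sample.int(40)
  ent2 <- entangle(Ff[perm, ], coords[perm, ], f_s, params_small)
  for (j in 1:4) {
    M <- ent1$q_entangle[[j]]
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
    expect_lt(max(abs(M - ent2$q_entangle[[j]])), 1e-7)
  }
})

test_that("dynamic convolution reduces to the residual path under a zero kernel", {
  set.seed(6)
  coords <- matrix(runif(60), ncol = 3)
  f_s <- rnorm(params_small$d_s)
  Ff <- fuse(build_template(f_s, params_small), trilinear_weights(coords))
  ent <- entangle(Ff, coords, f_s, params_small)

  p0 <- params_small
  p0$mlp_kernel$W2[] <- 0
  Y0 <- dynamic_conv_out(coords, 1:5, ent$q_states, ent$q_entangle, p0)
  expect_equal(Y0, coords %*% t(p0$W_skip), tolerance = 1e-12)

  Y <- dynamic_conv_out(coords, 1:20, ent$q_states, ent$q_entangle, params_small)
  expect_equal(dim(Y), c(20L * 0 + nrow(coords), params_small$d_out))

  # mean of the entanglement matrices matches a loop oracle
  M <- Reduce(`+`, ent$q_entangle) / 4
  M_oracle <- matrix(0, params_small$K, params_small$K)
  for (j in 1:4) for (a in seq_len(params_small$K)) for (b in seq_len(params_small$K)) {
    M_oracle[a, b] <- M_oracle[a, b] + ent$q_entangle[[j]][a, b] / 4
  }
  expect_lt(max(abs(M - M_oracle)), 1e-7)

  # empty gated subset: identity-kernel fallback is reported and finite
  expect_message(
    Ye <- dynamic_conv_out(coords, integer(0), ent$q_states, ent$q_entangle,
                           params_small),
    "identity")
  expect_true(all(is.finite(Ye)))
})

test_that("the full encoder block is deterministic and annotation-sensitive", {
  gen <- generate_plantation(plantation_spec(rows = 1, trees_per_row = 2,
                                             seed = 3))
  out1 <- encode_points(gen$pc, gen$annotations, params_small)
  out2 <- encode_points(gen$pc, gen$annotations, params_small)
  expect_identical(out1$features, out2$features)

  # 3D-only mode runs without annotations and differs from multimodal
  out3d <- encode_points(gen$pc, NULL, params_small)
  expect_equal(dim(out3d$features), dim(out1$features))
  expect_false(isTRUE(all.equal(out3d$features, out1$features)))
})
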