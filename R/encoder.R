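#' Parameters of the multimodal deformable encoder
#'
#' The encoder injects top-view crown-boundary cues into per-point 3D
#' features: the annotation JSON is summarized into a semantic vector,
#' expanded into an 8-vertex hypercube feature template, fused onto every
#' point by trilinear interpolation of its normalized coordinates, and then
#' refined by branch selection, sparse gating, subspace entanglement and a
#' dynamic convolution with a residual projection of the raw coordinates.
#' All weights are drawn once from seeded Gaussians (fan-in scaled); the
#' encoder has no internal randomness after construction.
#'
#' @param d_s Semantic vector length.
#' @param d_feat Template feature dimension (8 x `d_feat` template).
#' @param n_branch Number of convolutional branches for soft path selection.
#' @param K Subspace dimension; features reorganize into 4 subspaces of
#'   size `K`, so the state projection emits `4 * K` values per point.
#' @param d_out Output feature dimension per point.
#' @param tau_g Sparse-gating threshold in (0, 1); a point is retained when
#'   its gate score strictly exceeds `tau_g`.
#' @param hidden_mult Hidden width multiplier of the internal 2-layer MLPs.
#' @param activation `"tanh"` or `"relu"`.
#' @param residual_input `"coords"` (default) projects raw coordinates on
#'   the residual path; `"fused"` projects the fused features instead.
#' @param seed Integer seed for weight initialization.
#' @return An `encoder_params` list of weight matrices.
#' @export
encoder_params <- function(d_s = 64, d_feat = 64, n_branch = 3, K = 16,
                           d_out = 8, tau_g = 0.5, hidden_mult = 2,
                           activation = c("tanh", "relu"),
                           residual_input = c("coords", "fused"),
                           seed = 1L) {
  activation <- match.arg(activation)
  residual_input <- match.arg(residual_input)
  if (tau_g <= 0 || tau_g >= 1) stop("tau_g must lie in (0, 1)", call. = FALSE)
  n_desc <- 12L
  rng <- local_rng(seed)
  gauss <- function(nr, nc) rng(function() matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc))
  mlp <- function(d_in, d_out) {
    h <- hidden_mult * d_in
    list(W1 = gauss(h, d_in), b1 = rep(0, h),
         W2 = gauss(d_out, h), b2 = rep(0, d_out))
  }
  structure(list(
    d_s = d_s, d_feat = d_feat, n_branch = n_branch, K = K, d_out = d_out,
    tau_g = tau_g, activation = activation, residual_input = residual_input,
    n_desc = n_desc,
    W_proj = gauss(d_s, n_desc),
    mlp_hypercube = mlp(d_s, 8L * d_feat),
    mlp_b = mlp(d_feat, n_branch),
    mlp_g = mlp(3L + d_s, 1L),
    W_q = gauss(4L * K, d_feat + 3L + d_s),
    mlp_kernel = mlp(3L, K * d_out),
    W_skip = gauss(d_out, if (residual_input == "coords") 3L else d_feat)
  ), class = "encoder_params")
}

mlp_forward <- function(mlp, X, activation = "tanh") {
  act <- if (activation == "relu") function(v) pmax(v, 0) else tanh
  H <- act(X %*% t(mlp$W1) + matrix(mlp$b1, nrow(X), length(mlp$b1), byrow = TRUE))
  H %*% t(mlp$W2) + matrix(mlp$b2, nrow(X), length(mlp$b2), byrow = TRUE)
}

#' Encode a crown annotation set into a semantic vector
#'
#' Summarizes the annotation set by permutation-invariant descriptors
#' (polygon count, crown/background balance, mean and spread of polygon
#' area, perimeter, vertex count, equivalent diameter, centroid dispersion,
#' total area) and projects them through the learnable projection. An empty
#' set maps to the all-zero descriptor, which is valid input.
#'
#' @param ann A [crown_annotation_set()] or `NULL` for 3D-only operation
#'   (returns the zero vector).
#' @param params An [encoder_params()].
#' @return Numeric vector of length `params$d_s`.
#' @export
encode_json <- function(ann, params) {
  desc <- annotation_descriptor(ann)
  as.numeric(params$W_proj %*% desc)
}

annotation_descriptor <- function(ann) {
  if (is.null(ann) || nrow(ann$polygons) == 0) return(rep(0, 12))
  polys <- ann$polygons$polygon
  areas <- vapply(polys, polygon_area, 0)
  perims <- vapply(polys, polygon_perimeter, 0)
  nv <- vapply(polys, nrow, 0L)
  cents <- t(vapply(polys, colMeans, c(0, 0)))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  c(length(polys),
    mean(ann$polygons$label == "crown"),
    mean(areas), sd0(areas),
    mean(perims), sd0(perims),
    mean(nv), sd0(nv),
    sd0(cents[, 1]), sd0(cents[, 2]),
    mean(2 * sqrt(areas / pi)),
    sum(areas))
}

#' Build the hypercube feature template from a semantic vector
#'
#' Reshapes the MLP image of the semantic vector into an 8 x `d_feat`
#' matrix whose rows are the feature values at the template's eight
#' vertices, ordered to match the trilinear weight ordering of
#' [trilinear_weights()].
#'
#' @param f_s Semantic vector from [encode_json()].
#' @param params An [encoder_params()].
#' @return 8 x `d_feat` numeric matrix.
#' @export
build_template <- function(f_s, params) {
  stopifnot(all(is.finite(f_s)), length(f_s) == params$d_s)
  out <- mlp_forward(params$mlp_hypercube, matrix(f_s, 1), params$activation)
  matrix(out, 8L, params$d_feat)
}

#' Trilinear interpolation weights over the unit cube
#'
#' For normalized coordinates (x, y, z) in the unit cube the eight weights
#' are the trilinear basis functions at the cube corners, ordered
#' `w1 = (1-x)(1-y)(1-z)`, `w2 = x(1-y)(1-z)`, `w3 = (1-x)y(1-z)`,
#' `w4 = xy(1-z)`, `w5 = (1-x)(1-y)z`, `w6 = x(1-y)z`, `w7 = (1-x)yz`,
#' `w8 = xyz`. Rows always sum to 1. Coordinates outside the cube are
#' clamped with a warning; NaN coordinates are an error.
#'
#' @param norm_coords N x 3 matrix (or data frame with x, y, z) in
#'   `[0, 1]^3`.
#' @return N x 8 weight matrix.
#' @export
trilinear_weights <- function(norm_coords) {
  if (is.data.frame(norm_coords)) {
    norm_coords <- as.matrix(norm_coords[, c("x", "y", "z")])
  }
  if (any(is.nan(norm_coords))) stop("NaN coordinate in trilinear_weights", call. = FALSE)
  if (any(norm_coords < 0 | norm_coords > 1)) {
    warning("coordinates outside [0,1] clamped for trilinear interpolation")
    norm_coords <- pmin(pmax(norm_coords, 0), 1)
  }
  x <- norm_coords[, 1]; y <- norm_coords[, 2]; z <- norm_coords[, 3]
  cbind((1 - x) * (1 - y) * (1 - z),
        x       * (1 - y) * (1 - z),
        (1 - x) * y       * (1 - z),
        x       * y       * (1 - z),
        (1 - x) * (1 - y) * z,
        x       * (1 - y) * z,
        (1 - x) * y       * z,
        x       * y       * z)
}

#' Fuse the hypercube template onto points by weighted summation
#'
#' `F_fused[n, d] = sum_w W[n, w] * H[w, d]` -- a plain matrix product of
#' the interpolation weights with the template, linear in both arguments.
#'
#' @param template 8 x `d_feat` matrix from [build_template()].
#' @param weights N x 8 matrix from [trilinear_weights()].
#' @return N x `d_feat` fused feature matrix.
#' @export
fuse <- function(template, weights) {
  stopifnot(nrow(template) == 8L, ncol(weights) == 8L)
  weights %*% template
}

#' Soft branch-selection weights
#'
#' Per-point softmax over MLP logits of the fused features; each row is a
#' point's mixing distribution over the convolutional branches (rows sum
#' to 1). Branch outputs are combined by this weighted sum downstream.
#'
#' @param f_fused N x `d_feat` fused features.
#' @param params An [encoder_params()].
#' @return N x `n_branch` simplex-row matrix.
#' @export
select_branches <- function(f_fused, params) {
  logits <- mlp_forward(params$mlp_b, f_fused, params$activation)
  softmax_rows(logits)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Sparse semantic gating of points
#'
#' Gate scores are `sigmoid(MLP_g([p, F_s]))` with the semantic vector
#' broadcast to every point by concatenation with its normalized
#' coordinates. Points are retained when the score strictly exceeds
#' `tau_g`, so zero gate logits (score 0.5 everywhere) retain nothing at
#' the default threshold 0.5.
#'
#' @param norm_coords N x 3 normalized coordinates.
#' @param f_s Semantic vector.
#' @param params An [encoder_params()].
#' @param tau_g Gating threshold; defaults to `params$tau_g`.
#' @return List with `g_mask` (scores in `[0, 1]`) and `masked` (integer
#'   indices of retained points, possibly empty).
#' @export
sparse_gate <- function(norm_coords, f_s, params, tau_g = params$tau_g) {
  if (is.data.frame(norm_coords)) norm_coords <- as.matrix(norm_coords[, c("x", "y", "z")])
  n <- nrow(norm_coords)
  X <- cbind(norm_coords, matrix(f_s, n, length(f_s), byrow = TRUE))
  g <- stats::plogis(as.numeric(mlp_forward(params$mlp_g, X, params$activation)))
  list(g_mask = g, masked = which(g > tau_g))
}

#' Subspace entanglement of fused point states
#'
#' Projects `[F_fused, p, F_s]` to `4 * K` state values per point,
#' reorganized into 4 subspaces of size `K`, and forms per-subspace second
#' moment matrices `Q_j = (1/N) sum_i q_ij q_ij^T`, which are symmetric
#' positive semidefinite and invariant to point order.
#'
#' @param f_fused N x `d_feat` fused features.
#' @param norm_coords N x 3 normalized coordinates.
#' @param f_s Semantic vector.
#' @param params An [encoder_params()].
#' @return List with `q_states` (N x 4 x K array) and `q_entangle` (list of
#'   4 K x K matrices).
#' @export
entangle <- function(f_fused, norm_coords, f_s, params) {
  if (is.data.frame(norm_coords)) norm_coords <- as.matrix(norm_coords[, c("x", "y", "z")])
  n <- nrow(f_fused)
  K <- params$K
  X <- cbind(f_fused, norm_coords, matrix(f_s, n, length(f_s), byrow = TRUE))
  Q <- X %*% t(params$W_q)                       # N x 4K
  q_states <- array(0, dim = c(n, 4L, K))
  q_entangle <- vector("list", 4L)
  for (j in 1:4) {
    block <- Q[, ((j - 1) * K + 1):(j * K), drop = FALSE]
    q_states[, j, ] <- block
    q_entangle[[j]] <- crossprod(block) / n
  }
  list(q_states = q_states, q_entangle = q_entangle)
}

#' Dynamic convolution output with residual projection
#'
#' The dynamic kernel is the kernel MLP mean-pooled over the gated point
#' subset, reshaped to K x `d_out`; when the gated subset is empty the
#' kernel falls back to the identity embedding (logged via message). Each
#' point contributes its subspace-averaged state vector `s_n` (length K),
#' and the output is `Y = P W_skip^T + S M K_dyn` where `M` is the
#' elementwise mean of the four entanglement matrices. A zero kernel MLP
#' therefore reduces the output to the residual path alone.
#'
#' @param norm_coords N x 3 normalized coordinates.
#' @param masked Integer indices from [sparse_gate()].
#' @param q_states N x 4 x K state array from [entangle()].
#' @param q_entangle List of 4 K x K matrices from [entangle()].
#' @param params An [encoder_params()].
#' @return N x `d_out` output feature matrix.
#' @export
dynamic_conv_out <- function(norm_coords, masked, q_states, q_entangle, params) {
  if (is.data.frame(norm_coords)) norm_coords <- as.matrix(norm_coords[, c("x", "y", "z")])
  K <- params$K; d_out <- params$d_out
  if (length(masked) == 0) {
    message("sparse gate retained no points; dynamic kernel falls back to identity")
    k_dyn <- diag(1, K, d_out)
  } else {
    kv <- mlp_forward(params$mlp_kernel, norm_coords[masked, , drop = FALSE],
                      params$activation)
    k_dyn <- matrix(colMeans(kv), K, d_out)
  }
  M <- Reduce(`+`, q_entangle) / length(q_entangle)
  S <- apply(q_states, c(1, 3), mean)            # N x K, subspace average
  resid <- if (params$residual_input == "coords") norm_coords %*% t(params$W_skip)
           else stop("residual_input='fused' requires encode_points()", call. = FALSE)
  resid + S %*% M %*% k_dyn
}

#' Run the full multimodal encoder over a point cloud
#'
#' Normalizes the block, encodes the annotations (or runs 3D-only with a
#' zero semantic vector when `ann` is `NULL`), builds and fuses the
#' hypercube template, and applies branch selection, gating, entanglement
#' and dynamic convolution. Deterministic given `params`.
#'
#' @param pc A [point_cloud()].
#' @param ann A [crown_annotation_set()] or `NULL` (3D-only ablation mode).
#' @param params An [encoder_params()].
#' @return List with `features` (N x `d_out` matrix), `f_fused`,
#'   `branch_weights`, `g_mask`, `masked`, `f_s`.
#' @export
encode_points <- function(pc, ann = NULL, params = encoder_params()) {
  norm <- normalize_coords(pc)
  coords <- as.matrix(norm$pc[, c("x", "y", "z")])
  f_s <- encode_json(ann, params)
  H <- build_template(f_s, params)
  W <- trilinear_weights(coords)
  f_fused <- fuse(H, W)
  bw <- select_branches(f_fused, params)
  gate <- sparse_gate(coords, f_s, params)
  ent <- entangle(f_fused, coords, f_s, params)
  feats <- if (params$residual_input == "fused") {
    k_dyn <- if (length(gate$masked) == 0) diag(1, params$K, params$d_out) else {
      kv <- mlp_forward(params$mlp_kernel, coords[gate$masked, , drop = FALSE],
                        params$activation)
      matrix(colMeans(kv), params$K, params$d_out)
    }
    M <- Reduce(`+`, ent$q_entangle) / 4
    S <- apply(ent$q_states, c(1, 3), mean)
    f_fused %*% t(params$W_skip) + S %*% M %*% k_dyn
  } else {
    dynamic_conv_out(coords, gate$masked, ent$q_states, ent$q_entangle, params)
  }
  list(features = feats, f_fused = f_fused, branch_weights = bw,
       g_mask = gate$g_mask, masked = gate$masked, f_s = f_s)
}
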