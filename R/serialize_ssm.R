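#' Voxelize a point cloud
#'
#' Half-open binning: point p falls in voxel `k` on an axis when
#' `k * s <= coord - origin < (k + 1) * s`. The origin defaults to the
#' per-axis minimum so voxel coordinates are non-negative.
#'
#' @param pc A [point_cloud()] (or data frame with x, y, z).
#' @param voxel_size Edge length in metres (> 0).
#' @param origin Optional 3-vector; defaults to the coordinate minima.
#' @return A `voxel_grid` list: `voxel_coords` (M x 3 integer matrix of
#'   occupied voxels), `point_to_voxel` (N-vector of row indices into
#'   `voxel_coords`), `origin`, `voxel_size`.
#' @export
voxelize <- function(pc, voxel_size, origin = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive", call. = FALSE)
  xyz <- as.matrix(pc[, c("x", "y", "z")])
  origin <- origin %||% apply(xyz, 2, min)
  vc <- floor(sweep(sweep(xyz, 2, origin), 2, rep(voxel_size, 3), "/"))
  storage.mode(vc) <- "integer"
  if (any(vc < 0L)) stop("points below the voxel-grid origin", call. = FALSE)
  key <- as.numeric(vc[, 1]) +
    (max(vc[, 1]) + 1) * (as.numeric(vc[, 2]) + (max(vc[, 2]) + 1) * as.numeric(vc[, 3]))
  uk <- sort(unique(key))
  p2v <- match(key, uk)
  first <- match(uk, key)
  structure(list(voxel_coords = vc[first, , drop = FALSE],
                 point_to_voxel = p2v,
                 origin = origin, voxel_size = voxel_size),
            class = "voxel_grid")
}

#' Morton (Z-order) encoding of voxel coordinates
#'
#' Interleaves the binary digits of (x, y, z): bit `i` of x lands at output
#' bit `3i`, of y at `3i + 1`, of z at `3i + 2`. Injective on
#' `[0, 2^b)^3`; sorting by the code gives a locality-preserving 1D order.
#'
#' @param voxel_coords M x 3 non-negative integer matrix.
#' @param b Bits per axis (1..10; codes stay below 2^30 so they remain
#'   exact R integers). All coordinates must be `< 2^b`.
#' @return Integer vector of Morton codes.
#' @export
zorder_encode <- function(voxel_coords, b) {
  stopifnot(b >= 1, b <= 10)
  vc <- voxel_coords
  if (is.null(dim(vc))) vc <- matrix(vc, ncol = 3)
  storage.mode(vc) <- "integer"
  lim <- bitwShiftL(1L, b)
  for (ax in 1:3) {
    if (any(vc[, ax] >= lim)) {
      stop(sprintf("%s coordinate >= 2^%d in zorder_encode", c("x", "y", "z")[ax], b),
           call. = FALSE)
    }
  }
  z <- integer(nrow(vc))
  for (i in 0:(b - 1)) {
    z <- z + bitwShiftL(bitwAnd(vc[, 1], bitwShiftL(1L, i)), 2L * i) +
             bitwShiftL(bitwAnd(vc[, 2], bitwShiftL(1L, i)), 2L * i + 1L) +
             bitwShiftL(bitwAnd(vc[, 3], bitwShiftL(1L, i)), 2L * i + 2L)
  }
  z
}

#' Build a Z-order serialization sequence for a voxel grid
#'
#' Chooses the minimal `b` covering the grid extent (shared across axes),
#' encodes every occupied voxel, and records the sorting permutation and
#' its inverse. Ties (impossible for distinct voxels, the code is
#' injective) would break by original index.
#'
#' @param voxel_coords M x 3 integer matrix of occupied voxels.
#' @param b Bits per axis; minimal covering value by default.
#' @return A `zorder_sequence`: `b`, `z_index`, `perm`, `inv_perm` with
#'   `perm[inv_perm] == seq_len(M)`.
#' @export
zorder_sequence <- function(voxel_coords, b = NULL) {
  if (is.null(dim(voxel_coords))) voxel_coords <- matrix(voxel_coords, ncol = 3)
  b <- b %||% max(1, ceiling(log2(max(voxel_coords) + 1)))
  z <- zorder_encode(voxel_coords, b)
  perm <- order(z, seq_along(z))
  structure(list(b = b, z_index = z, perm = perm, inv_perm = order(perm)),
            class = "zorder_sequence")
}

#' Serialize per-voxel features into Z order
#'
#' @param features M x d feature matrix aligned with the voxel order used
#'   to build `seq`.
#' @param seq A [zorder_sequence()].
#' @return Features permuted by ascending Morton code.
#' @export
serialize <- function(features, seq) {
  stopifnot(inherits(seq, "zorder_sequence"))
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (nrow(features) != length(seq$perm)) {
    stop("feature row count does not match the serialization length", call. = FALSE)
  }
  features[seq$perm, , drop = FALSE]
}

#' Restore serialized features to the original voxel order
#'
#' `restore(serialize(x)) == x` exactly.
#'
#' @param y_norm Features in serialized order.
#' @param seq A [zorder_sequence()].
#' @return Features in original voxel order.
#' @export
restore <- function(y_norm, seq) {
  stopifnot(inherits(seq, "zorder_sequence"))
  if (is.null(dim(y_norm))) y_norm <- matrix(y_norm, ncol = 1)
  if (nrow(y_norm) != length(seq$perm)) {
    stop("feature row count does not match the serialization length", call. = FALSE)
  }
  y_norm[seq$inv_perm, , drop = FALSE]
}

#' Construct a selective state-space block
#'
#' A Mamba-style block: the state matrix `A` is static (negative,
#' stability-preserving initialization) and the step size, input and output
#' projections are input-dependent linear maps with
#' `delta = softplus(delta_hat) > 0`. The feed-through `D` is initialized
#' to 1.
#'
#' @param d Feature dimension of the sequence.
#' @param n_state State dimension per channel.
#' @param seed Seed for the projection weights.
#' @return An `ssm_block` parameter list.
#' @export
ssm_block <- function(d, n_state = 8, seed = 1L) {
  rng <- local_rng(seed)
  gauss <- function(nr, nc) rng(function() matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc))
  structure(list(
    d = d, n_state = n_state,
    A = -matrix(seq_len(n_state), d, n_state, byrow = TRUE),
    D = rep(1, d),
    W_dt = gauss(d, d), b_dt = rep(0, d),
    W_B = gauss(n_state, d),
    W_C = gauss(n_state, d)
  ), class = "ssm_block")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Selective state-space scan over a serialized sequence
#'
#' Input-dependent parameters come from linear projections of the input:
#' `delta_t = softplus(u_t W_dt + b_dt)`, `B_t = u_t W_B`, `C_t = u_t W_C`.
#' The `"sequential"` mode evaluates the reference recurrence
#' `x_t = exp(delta_t A) * x_{t-1} + (delta_t u_t) B_t`,
#' `y_t = x_t C_t + D u_t` per channel. The `"parallel"` mode evaluates the
#' literal cumulative-sum form `X = cumsum(exp(dA) * dB * u)`,
#' `y = C X + D u`; the two coincide exactly in the `A = 0` limit (where
#' the recurrence is a pure running sum) but not for general `A`, so the
#' sequential form is the reference implementation.
#'
#' @param u T x d input sequence.
#' @param block An [ssm_block()].
#' @param mode `"sequential"` or `"parallel"`.
#' @return T x d output sequence.
#' @export
selective_scan <- function(u, block, mode = c("sequential", "parallel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(block, "ssm_block"))
  if (is.null(dim(u))) u <- matrix(u, ncol = 1)
  if (ncol(u) != block$d) stop("input feature dimension mismatch", call. = FALSE)
  T_len <- nrow(u); d <- block$d; n <- block$n_state
  dt <- softplus(u %*% t(block$W_dt) +
                   matrix(block$b_dt, T_len, d, byrow = TRUE))   # T x d
  B <- u %*% t(block$W_B)                                        # T x n
  C <- u %*% t(block$W_C)                                        # T x n
  if (any(!is.finite(dt)) || any(!is.finite(B)) || any(!is.finite(C))) {
    bad <- which(rowSums(!is.finite(cbind(dt, B, C))) > 0)[1]
    stop(sprintf("non-finite scan parameter at step %d", bad), call. = FALSE)
  }
  y <- matrix(0, T_len, d)
  if (mode == "sequential") {
    x <- matrix(0, d, n)
    for (t in seq_len(T_len)) {
      x <- exp(block$A * dt[t, ]) * x + (dt[t, ] * u[t, ]) %o% B[t, ]
      y[t, ] <- x %*% C[t, ] + block$D * u[t, ]
    }
  } else {
    for (s in seq_len(n)) {
      Es <- exp(dt * matrix(block$A[, s], T_len, d, byrow = TRUE))
      Gs <- (dt * u) * B[, s]
      Xs <- apply(Es * Gs, 2, cumsum)
      if (T_len == 1) Xs <- matrix(Xs, 1)
      y <- y + Xs * C[, s]
    }
    y <- y + sweep(u, 2, block$D, `*`)
  }
  y
}

#' Root-mean-square normalization
#'
#' `y_norm = y / sqrt(mean(y^2) + eps) * w` per row: each feature row is
#' divided by its RMS, then scaled elementwise by the trainable `w`.
#' Scale-invariant for positive scalings when `eps = 0`.
#'
#' @param y T x d matrix (or vector, treated as one row).
#' @param w Scale vector of length d (default 1).
#' @param eps Small stabilizer (> 0 in training; tests may pass 0).
#' @return Normalized matrix of the same shape.
#' @export
rmsnorm <- function(y, w = 1, eps = 1e-8) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, nrow = 1)
  rms <- sqrt(rowMeans(y^2) + eps)
  out <- sweep(y / rms, 2, rep_len(w, ncol(y)), `*`)
  if (vec) out[1, ] else out
}

#' Voxel-pooled selective-scan features for a point cloud
#'
#' Voxelizes the cloud, mean-pools per-point features into voxels,
#' serializes voxels by Morton code, runs the selective scan and RMSNorm,
#' restores spatial order, and scatters the voxel features back to member
#' points, preserving the point count.
#'
#' @param pc A [point_cloud()].
#' @param features N x d per-point input features.
#' @param voxel_size Metres (default 0.2).
#' @param block An [ssm_block()] with `d` matching `features`.
#' @param mode Scan mode, see [selective_scan()].
#' @param w,eps RMSNorm parameters.
#' @return N x d per-point output features.
#' @export
ssm_encode <- function(pc, features, voxel_size = 0.2,
                       block = NULL, mode = "sequential",
                       w = 1, eps = 1e-8) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  block <- block %||% ssm_block(ncol(features))
  grid <- voxelize(pc, voxel_size)
  M <- nrow(grid$voxel_coords)
  pooled <- rowsum(features, grid$point_to_voxel) /
    as.vector(table(factor(grid$point_to_voxel, levels = seq_len(M))))
  zseq <- zorder_sequence(grid$voxel_coords)
  y <- serialize(pooled, zseq) |>
    selective_scan(block, mode) |>
    rmsnorm(w = w, eps = eps) |>
    restore(zseq)
  y[grid$point_to_voxel, , drop = FALSE]
}
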