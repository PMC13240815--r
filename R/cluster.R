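#' Choose the clustering backend by segment size
#'
#' Small segments use a k-nearest-neighbour connectivity backend (cheap,
#' effective when crowns are spatially separable); at or above the
#' threshold a mean-shift backend is used (robust mode seeking for large,
#' structurally complex segments). The boundary goes to mean shift.
#'
#' @param pc A [point_cloud()] (the segment).
#' @param size_threshold Point-count threshold (default 5000).
#' @return `"knn"` or `"meanshift"`.
#' @export
select_backend <- function(pc, size_threshold = 5000) {
  stopifnot(nrow(pc) >= 1)
  if (nrow(pc) < size_threshold) "knn" else "meanshift"
}

#' Levy-flight step sampler
#'
#' Heavy-tailed exploration steps `step = u / |v|^(1/beta)` with
#' `u ~ N(0, sigma^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma = (Gamma(1+beta) sin(pi beta / 2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2)))^(1/beta)`. The default
#' `beta = 1.5` gives `sigma ~ 0.6966`.
#'
#' @param dim Number of components to draw.
#' @param beta Stability parameter in (0, 2].
#' @return Numeric step vector of length `dim`.
#' @export
levy_step <- function(dim = 1, beta = 1.5) {
  stopifnot(beta > 0, beta <= 2)
  sigma <- levy_sigma(beta)
  u <- stats::rnorm(dim, 0, sigma)
  v <- stats::rnorm(dim)
  while (any(v == 0)) v[v == 0] <- stats::rnorm(sum(v == 0))
  u / abs(v)^(1 / beta)
}

#' @rdname levy_step
#' @export
levy_sigma <- function(beta = 1.5) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Dynamic search-range control factor
#'
#' `E = 2 * ln(1/random()) * theta` with
#' `theta = 2 * arctan(1 - iteration / max_iter)`; `E` shrinks to exactly 0
#' at the final iteration, and the optimizer switches from global
#' exploration to local exploitation when `E <= 1`.
#'
#' @param iteration Current iteration (0..`max_iter`).
#' @param max_iter Maximum iterations (>= 1).
#' @return Non-negative scalar `E`.
#' @export
control_factor <- function(iteration, max_iter) {
  stopifnot(max_iter >= 1, iteration >= 0, iteration <= max_iter)
  theta <- 2 * atan(1 - iteration / max_iter)
  2 * log(1 / stats::runif(1)) * theta
}

#' Exploitation updates of the clustering parameter vector
#'
#' Two mechanisms, applied when the control factor signals exploitation:
#' `"ds"`: `theta_new = theta_best + F * R * B * r1 * (theta_best -
#' theta_current)`; `"gft"`: `theta_new = theta_current + F * r2 *
#' (theta_best - theta_current)`. `R`, `B` are standard-normal perturbation
#' draws and `r1`, `r2` uniform draws. The result is clamped to the bounds;
#' `theta_current == theta_best` is a fixed point of both.
#'
#' @param theta_current,theta_best Parameter vectors.
#' @param bounds 2 x p matrix, rows = lower/upper.
#' @param variant `"ds"` or `"gft"`.
#' @param f_scale Scaling factor F (default 0.5).
#' @return Updated, clamped parameter vector.
#' @export
exploit_update <- function(theta_current, theta_best, bounds,
                           variant = c("ds", "gft"), f_scale = 0.5) {
  variant <- match.arg(variant)
  p <- length(theta_current)
  theta_new <- if (variant == "ds") {
    R <- stats::rnorm(p); B <- stats::rnorm(p); r1 <- stats::runif(1)
    theta_best + f_scale * R * B * r1 * (theta_best - theta_current)
  } else {
    r2 <- stats::runif(1)
    theta_current + f_scale * r2 * (theta_best - theta_current)
  }
  clamp_theta(theta_new, bounds)
}

#' Spiral local-search update
#'
#' `radius = ||theta_best - theta_current||`, `spiral = radius *
#' (sin(2 pi r3) + cos(2 pi r3))`, `theta_new = theta_best + F *
#' theta_current * spiral * random()`, clamped to bounds. When current and
#' best coincide the radius is zero and the update is the fixed point
#' `theta_best`; `|spiral| <= radius * sqrt(2)` always.
#'
#' @inheritParams exploit_update
#' @return Updated, clamped parameter vector.
#' @export
spiral_update <- function(theta_current, theta_best, bounds, f_scale = 0.5) {
  radius <- sqrt(sum((theta_best - theta_current)^2))
  r3 <- stats::runif(1)
  spiral <- radius * (sin(2 * pi * r3) + cos(2 * pi * r3))
  theta_new <- theta_best + f_scale * theta_current * spiral * stats::runif(1)
  clamp_theta(theta_new, bounds)
}

clamp_theta <- function(theta, bounds) {
  pmin(pmax(theta, bounds[1, ]), bounds[2, ])
}

#' Feedback score combining mean and best per-sample F-scores
#'
#' `score = alpha * mean(f1) + (1 - alpha) * max(f1)` with `alpha = 0.7`.
#' A candidate parameter vector is accepted only when this score strictly
#' exceeds the historical best.
#'
#' @param f1_per_sample Non-empty vector of per-sample F-scores in [0, 1].
#' @param alpha Weight of the mean term.
#' @return Scalar score between `min` and `max` of its inputs.
#' @export
feedback_score <- function(f1_per_sample, alpha = 0.7) {
  if (length(f1_per_sample) == 0) stop("empty F-score vector", call. = FALSE)
  stopifnot(all(f1_per_sample >= 0 & f1_per_sample <= 1))
  alpha * mean(f1_per_sample) + (1 - alpha) * max(f1_per_sample)
}

# ---- clustering backends --------------------------------------------------

#' k-nearest-neighbour connectivity clustering
#'
#' Connects every point to its `k` nearest neighbours within
#' `merge_dist` and labels connected components. Suited to small segments.
#'
#' @param pc A [point_cloud()] segment.
#' @param k Neighbour count (rounded, >= 1).
#' @param merge_dist Maximum edge length in metres.
#' @return Integer vector of instance labels (1..M) for the rows of `pc`.
#' @export
cluster_knn <- function(pc, k, merge_dist) {
  xyz <- as.matrix(pc[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 1) return(1L)
  k <- max(1L, min(as.integer(round(k)), n - 1L))
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- Inf
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    nb <- nb[D[i, nb] <= merge_dist]
    if (length(nb)) edges[[i]] <- rbind(i, nb)
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)$membership
  relabel_by_size(comp)
}

#' Flat-kernel mean-shift clustering in the horizontal plane
#'
#' Crown instances of row-planted trees are modes of the projected XY
#' point density. Seeds are placed on a grid of occupied bandwidth-sized
#' bins (bin seeding), shifted to the local flat-kernel mean until
#' convergence, and modes closer than the bandwidth are merged
#' (higher-support mode wins). Every point is assigned to its nearest
#' mode; clusters smaller than `min_size` are dissolved into the nearest
#' surviving mode.
#'
#' @param pc A [point_cloud()] segment.
#' @param bandwidth Kernel radius in metres.
#' @param min_size Minimum cluster size in points.
#' @param max_iter Maximum shift iterations per seed.
#' @return Integer vector of instance labels (1..M) for the rows of `pc`.
#' @export
cluster_meanshift <- function(pc, bandwidth, min_size = 1, max_iter = 30) {
  xy <- as.matrix(pc[, c("x", "y")])
  n <- nrow(xy)
  bw <- max(bandwidth, 1e-6)
  seed_bin <- max(bw, 1)   # coarse bin seeding keeps the seed count bounded
  bins <- floor(sweep(xy, 2, apply(xy, 2, min)) / seed_bin)
  key <- bins[, 1] + (max(bins[, 1]) + 1) * bins[, 2]
  seed_idx <- match(sort(unique(key)), key)
  seeds <- (bins[seed_idx, , drop = FALSE] + 0.5) * seed_bin +
    matrix(apply(xy, 2, min), length(seed_idx), 2, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(seeds^2), rowSums(xy^2), `+`) - 2 * seeds %*% t(xy)
    within <- d2 <= bw^2
    cnt <- rowSums(within)
    cnt[cnt == 0] <- 1
    new_seeds <- cbind(within %*% xy[, 1], within %*% xy[, 2]) / cnt
    moved <- max(rowSums((new_seeds - seeds)^2))
    seeds <- new_seeds
    if (moved < 1e-6 * bw^2) break
  }
  # merge modes within one bandwidth, strongest support first
  d2s <- outer(rowSums(seeds^2), rowSums(xy^2), `+`) - 2 * seeds %*% t(xy)
  support <- rowSums(d2s <= bw^2)
  ord <- order(-support, seeds[, 1], seeds[, 2])
  modes <- matrix(0, 0, 2)
  for (i in ord) {
    if (nrow(modes) == 0 ||
        min(rowSums(sweep(modes, 2, seeds[i, ])^2)) > bw^2) {
      modes <- rbind(modes, seeds[i, ])
    }
  }
  d2m <- outer(rowSums(xy^2), rowSums(modes^2), `+`) - 2 * xy %*% t(modes)
  lab <- max.col(-d2m, ties.method = "first")
  # dissolve undersized clusters into the nearest surviving mode
  sizes <- tabulate(lab, nbins = nrow(modes))
  keep <- which(sizes >= max(1, min_size))
  if (length(keep) == 0) keep <- which.max(sizes)
  if (length(keep) < nrow(modes)) {
    d2k <- d2m[, keep, drop = FALSE]
    lab <- keep[max.col(-d2k, ties.method = "first")]
  }
  relabel_by_size(lab)
}

#' Density-connectivity clustering (DBSCAN-style drop-in)
#'
#' Connects points within `eps` of each other (via voxel-grid hashing) and
#' labels connected components; components smaller than `min_pts` become
#' background (0). Provided as an ablation replacement for the adaptive
#' optimizer.
#'
#' @param pc A [point_cloud()] segment.
#' @param eps Connection radius in metres.
#' @param min_pts Minimum component size.
#' @return Integer labels (0 for noise).
#' @export
cluster_connectivity <- function(pc, eps, min_pts = 1) {
  xyz <- as.matrix(pc[, c("x", "y", "z")])
  n <- nrow(xyz)
  grid <- voxelize(pc, eps)
  vc <- grid$voxel_coords
  M <- nrow(vc)
  key <- function(m) as.numeric(m[, 1]) + 1e5 * (as.numeric(m[, 2]) + 1e5 * as.numeric(m[, 3]))
  vkey <- key(vc)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pairs <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vc, 2, -as.integer(offs[r, ]))
    hit <- match(key(nb), vkey)
    ok <- which(!is.na(hit) & hit > seq_len(M))
    if (length(ok)) pairs[[length(pairs) + 1]] <- cbind(ok, hit[ok])
  }
  g <- igraph::make_empty_graph(M, directed = FALSE)
  if (length(pairs)) {
    em <- do.call(rbind, pairs)
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  vox_comp <- igraph::components(g)$membership
  lab <- vox_comp[grid$point_to_voxel]
  sizes <- tabulate(lab)
  lab[sizes[lab] < min_pts] <- 0L
  pos <- lab > 0L
  lab[pos] <- relabel_by_size(lab[pos])
  as.integer(lab)
}

relabel_by_size <- function(lab) {
  sizes <- table(lab)
  ord <- names(sizes)[order(-as.vector(sizes), as.numeric(names(sizes)))]
  as.integer(match(as.character(lab), ord))
}

cluster_with_theta <- function(pc, theta, backend, min_size_default = 1) {
  if (backend == "knn") {
    cluster_knn(pc, k = theta[1], merge_dist = theta[2])
  } else {
    cluster_meanshift(pc, bandwidth = theta[1],
                      min_size = max(1, round(theta[2])))
  }
}

# Default search bounds per backend. The minimum-cluster-size bound scales
# with the number of clustered items m: allowing it to approach the typical
# cluster size would let the search dissolve genuine crowns.
default_bounds <- function(backend, m = 1e4) {
  if (backend == "knn") rbind(c(2, 0.2), c(20, 3))
  else rbind(c(0.5, 1), c(4, max(2, sqrt(m))))
}

# ---- the closed-loop optimizer -------------------------------------------

#' Adaptive clustering-parameter optimization
#'
#' The closed-loop refinement stage: clustering hyperparameters are
#' searched by a lemming-style metaheuristic -- Levy-flight global
#' exploration while the control factor `E > 1`, then DS/GFT exploitation
#' updates with spiral local refinement when `E <= 1` -- and a candidate is
#' accepted only when the feedback score (`0.7 * mean F1 + 0.3 * max F1`
#' over validation samples) strictly exceeds the incumbent. The incumbent
#' score is therefore non-decreasing, and the whole run is reproducible
#' given `seed`.
#'
#' The backend works on the crown (foreground) points only; background
#' points keep instance 0. For speed, clustering operates on a voxel
#' down-sampled cloud and labels are scattered back to the member points.
#'
#' @param pc A [point_cloud()] with `semantic` labels (predicted or true);
#'   points with `semantic == 1` are clustered.
#' @param val_fn Scorer: takes the full-length instance label vector and
#'   returns per-sample F-scores in [0, 1]. See
#'   [make_supervised_scorer()] and [make_proxy_scorer()].
#' @param bounds Optional 2 x 2 matrix of per-component lower/upper bounds
#'   for the backend's parameter pair (knn: neighbour count, merge
#'   distance; meanshift: bandwidth, min cluster size).
#' @param max_iter Search budget (default 50).
#' @param seed Integer seed.
#' @param size_threshold Backend switch point, see [select_backend()].
#' @param backend Force `"knn"` or `"meanshift"` instead of size-aware
#'   selection.
#' @param downsample Voxel size (m) for the clustering subsample.
#' @param f_scale Scaling factor F of the exploitation updates.
#' @param alpha Feedback-score weight.
#' @return An `aloc_fit`: `instance` (full-length labels, 0 background),
#'   `theta_best`, `best_score`, `backend`, `trajectory` (tibble per
#'   iteration: phase, candidate score, incumbent score).
#' @export
optimize_clustering <- function(pc, val_fn, bounds = NULL, max_iter = 50,
                                seed = 1L, size_threshold = 5000,
                                backend = NULL, downsample = 0.4,
                                f_scale = 0.5, alpha = 0.7) {
  stopifnot(!is.null(pc[["semantic"]]))
  fg_idx <- which(pc[["semantic"]] == 1L)
  if (length(fg_idx) == 0) {
    warning("no foreground points; returning empty segmentation")
    return(structure(list(instance = rep(0L, nrow(pc)), theta_best = NULL,
                          best_score = NA_real_, backend = NA_character_,
                          trajectory = tibble::tibble()), class = "aloc_fit"))
  }
  fg <- pc[fg_idx, ]
  backend <- backend %||% select_backend(fg, size_threshold)

  # voxel subsample for clustering speed; labels scatter back to points
  grid <- voxelize(fg, downsample)
  centers <- tibble::as_tibble(as.data.frame(
    (grid$voxel_coords + 0.5) * grid$voxel_size +
      matrix(grid$origin, nrow(grid$voxel_coords), 3, byrow = TRUE)))
  names(centers) <- c("x", "y", "z")
  sub_backend <- if (backend == "knn") "knn" else "meanshift"
  bounds <- bounds %||% default_bounds(backend, nrow(centers))
  assemble <- function(sub_lab) {
    inst <- rep(0L, nrow(pc))
    inst[fg_idx] <- sub_lab[grid$point_to_voxel]
    inst
  }
  score_theta <- function(theta) {
    lab <- cluster_with_theta(centers, theta, sub_backend)
    inst <- assemble(lab)
    f1 <- val_fn(inst)
    list(score = feedback_score(f1, alpha), inst = inst)
  }

  rng <- local_rng(seed)
  range_vec <- bounds[2, ] - bounds[1, ]
  theta_current <- bounds[1, ] + range_vec / 2
  init <- score_theta(theta_current)
  theta_best <- theta_current
  best_score <- init$score
  best_inst <- init$inst
  traj <- vector("list", max_iter)
  for (it in seq_len(max_iter)) {
    E <- rng(function() control_factor(it - 1, max_iter))
    theta_new <- if (E > 1) {
      step <- rng(function() levy_step(length(theta_current)))
      clamp_theta(theta_best + step * range_vec / 10, bounds)
    } else {
      variant <- rng(function() sample(c("ds", "gft"), 1))
      cand <- rng(function() exploit_update(theta_current, theta_best, bounds,
                                            variant, f_scale))
      if (rng(function() stats::runif(1)) < 0.5) {
        cand <- rng(function() spiral_update(cand, theta_best, bounds, f_scale))
      }
      cand
    }
    res <- score_theta(theta_new)
    accepted <- res$score > best_score
    if (accepted) {
      theta_best <- theta_new
      best_score <- res$score
      best_inst <- res$inst
    }
    theta_current <- theta_new
    traj[[it]] <- tibble::tibble(iteration = it, E = E,
                                 phase = if (E > 1) "explore" else "exploit",
                                 candidate_score = res$score,
                                 best_score = best_score,
                                 accepted = accepted)
  }
  structure(list(instance = as.integer(best_inst), theta_best = theta_best,
                 best_score = best_score, backend = backend,
                 trajectory = dplyr::bind_rows(traj)),
            class = "aloc_fit")
}

#' Supervised per-sample F-score feedback for the optimizer
#'
#' Builds a `val_fn` that matches candidate instances against ground-truth
#' labels at IoU `tau` and returns one F-score per validation sample
#' (per block when block ids are supplied, else one global sample).
#'
#' @param gt_instance Ground-truth instance vector aligned with the cloud.
#' @param tau IoU threshold (default 0.5).
#' @param blocks Optional per-point block ids defining validation samples.
#' @return A function `instance -> numeric vector of F-scores`.
#' @export
make_supervised_scorer <- function(gt_instance, tau = 0.5, blocks = NULL) {
  force(gt_instance); force(tau); force(blocks)
  function(instance) {
    if (is.null(blocks)) {
      m <- match_instances(instance, gt_instance, tau = tau)
      return(glance_f(m))
    }
    vapply(split(seq_along(instance), blocks), function(idx) {
      glance_f(match_instances(instance[idx], gt_instance[idx], tau = tau))
    }, 0)
  }
}

glance_f <- function(m) f_score(m$precision, m$recall)

#' Unsupervised proxy feedback (silhouette-style separation)
#'
#' For inference without labels: scores a candidate clustering by the
#' mean silhouette of cluster centroids in XY (separation between crowns
#' against their spread), mapped to [0, 1]. This proxy is a pragmatic
#' stand-in for supervised feedback and is not part of the evaluated
#' method; prefer [make_supervised_scorer()] whenever validation labels
#' exist.
#'
#' @param pc The [point_cloud()] being segmented.
#' @param sample_frac Fraction of points used (for speed).
#' @return A function `instance -> single proxy score in [0, 1]`.
#' @export
make_proxy_scorer <- function(pc, sample_frac = 0.2) {
  xy <- as.matrix(pc[, c("x", "y")])
  force(sample_frac)
  function(instance) {
    idx <- which(instance > 0L)
    if (length(idx) < 4 || length(unique(instance[idx])) < 2) return(0.5)
    keep <- idx[seq(1, length(idx), by = max(1, round(1 / sample_frac)))]
    lab <- instance[keep]
    if (length(unique(lab)) < 2) return(0.5)
    pts <- xy[keep, , drop = FALSE]
    cent <- rowsum(pts, lab) / as.vector(table(lab))
    labs <- sort(unique(lab))
    a <- sqrt(rowSums((pts - cent[match(lab, labs), , drop = FALSE])^2))
    d2 <- outer(rowSums(pts^2), rowSums(cent^2), `+`) - 2 * pts %*% t(cent)
    d2[cbind(seq_along(lab), match(lab, labs))] <- Inf
    b <- sqrt(pmax(apply(d2, 1, min), 0))
    sil <- (b - a) / pmax(a, b, 1e-9)
    sil <- sil[is.finite(sil)]
    if (length(sil) == 0) return(0.5)
    (mean(sil) + 1) / 2
  }
}
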