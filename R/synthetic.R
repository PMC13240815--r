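#' Specify a synthetic plantation
#'
#' Describes the structural regime of a row-planted rubber plantation:
#' regular planting grid, ellipsoidal crowns that may interpenetrate along
#' the row, cylindrical trunks, a strong vertical density gradient (dense
#' canopy, sparse trunk returns), a mixture of growth stages, sparse ground
#' returns, and additive coordinate noise. Defaults reflect a managed
#' mature rubber stand (3 m in-row spacing, 7 m between rows, 12-16 m
#' mature height, 1.5-2.5 m crown radius, 10:1 canopy:trunk volumetric
#' point density).
#'
#' @param rows,trees_per_row Planting grid dimensions.
#' @param row_spacing,tree_spacing Metres between rows / between trees in a
#'   row.
#' @param crown_radius_range,height_range Metres, for mature trees; young
#'   trees are scaled by `young_scale`.
#' @param overlap_factor Fraction of the half-spacing by which adjacent
#'   crowns may interpenetrate along the row; 0 keeps adjacent crowns
#'   disjoint in XY.
#' @param canopy_density,trunk_density Points per cubic metre; canopy must
#'   exceed trunk (the vertical gradient of UAV plantation returns).
#' @param ground_density Ground returns per square metre (semantic 0).
#' @param growth_stage_mix Named proportions for `mature` and `young`;
#'   must sum to 1.
#' @param young_scale Height/radius multiplier for young trees.
#' @param noise_sd Gaussian coordinate noise, metres.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `plantation_spec` list.
#' @export
plantation_spec <- function(rows = 4, trees_per_row = 5,
                            row_spacing = 7, tree_spacing = 3,
                            crown_radius_range = c(1.5, 2.5),
                            height_range = c(12, 16),
                            overlap_factor = 0.1,
                            canopy_density = 50, trunk_density = 5,
                            ground_density = 1,
                            growth_stage_mix = c(mature = 0.8, young = 0.2),
                            young_scale = 0.5,
                            noise_sd = 0.02,
                            seed = 1L) {
  if (rows * trees_per_row < 1) stop("spec yields zero trees", call. = FALSE)
  if (canopy_density <= 0 || trunk_density <= 0) {
    stop("densities must be positive", call. = FALSE)
  }
  if (canopy_density <= trunk_density) {
    stop("canopy_density must exceed trunk_density", call. = FALSE)
  }
  if (abs(sum(growth_stage_mix) - 1) > 1e-8) {
    stop("growth_stage_mix proportions must sum to 1", call. = FALSE)
  }
  structure(list(rows = rows, trees_per_row = trees_per_row,
                 row_spacing = row_spacing, tree_spacing = tree_spacing,
                 crown_radius_range = crown_radius_range,
                 height_range = height_range,
                 overlap_factor = overlap_factor,
                 canopy_density = canopy_density,
                 trunk_density = trunk_density,
                 ground_density = ground_density,
                 growth_stage_mix = growth_stage_mix,
                 young_scale = young_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "plantation_spec")
}

#' Generate a labelled synthetic plantation block
#'
#' Trees sit on a regular grid. Each tree is an ellipsoidal crown over a
#' cylindrical trunk; crown points are sampled uniformly inside the
#' ellipsoid at `canopy_density`, trunk points inside the cylinder at
#' `trunk_density`, and ground returns on the z = 0 plane at
#' `ground_density`. Crown points get `semantic = 1` and the tree's
#' instance id; trunk and ground points get `semantic = 0`, `instance = 0`.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [plantation_spec()].
#' @return A list with `pc` (the labelled [point_cloud()]), `annotations`
#'   (the paired top-view [crown_annotation_set()]) and `ground_truth`
#'   (tibble: `instance_id`, `x`, `y`, `height` = realized max z,
#'   `shape_height` = analytic shape height, `crown_diameter`,
#'   `crown_volume`, `crown_base`, `stage`).
#' @export
generate_plantation <- function(spec) {
  stopifnot(inherits(spec, "plantation_spec"))
  n_trees <- spec$rows * spec$trees_per_row
  rng <- local_rng(spec$seed)
  grid <- expand.grid(row = seq_len(spec$rows), col = seq_len(spec$trees_per_row))
  cx <- (grid$col - 1) * spec$tree_spacing
  cy <- (grid$row - 1) * spec$row_spacing

  stages <- rng(function() sample(names(spec$growth_stage_mix), n_trees,
                                  replace = TRUE, prob = spec$growth_stage_mix))
  scale <- ifelse(stages == "young", spec$young_scale, 1)
  h_shape <- rng(function() stats::runif(n_trees, spec$height_range[1],
                                         spec$height_range[2])) * scale
  r_raw <- rng(function() stats::runif(n_trees, spec$crown_radius_range[1],
                                       spec$crown_radius_range[2])) * scale
  # cap the XY radius so interpenetration along the row is exactly governed
  # by overlap_factor (0 => adjacent crowns disjoint)
  r_cap <- (spec$tree_spacing / 2) * (1 + spec$overlap_factor)
  if (spec$overlap_factor == 0) r_cap <- r_cap * 0.98
  r_xy <- pmin(r_raw, r_cap)

  pts <- vector("list", n_trees)
  gt <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    crown_base <- 0.55 * h_shape[i]
    c_semi <- (h_shape[i] - crown_base) / 2
    c_z0 <- crown_base + c_semi
    vol <- 4 / 3 * pi * r_xy[i]^2 * c_semi
    n_crown <- max(4L, rng(function() stats::rpois(1, vol * spec$canopy_density)))
    crown <- rng(function() sample_ellipsoid(n_crown, r_xy[i], r_xy[i], c_semi))
    crown[, 1] <- crown[, 1] + cx[i]
    crown[, 2] <- crown[, 2] + cy[i]
    crown[, 3] <- crown[, 3] + c_z0
    trunk_r <- 0.15 * scale[i]
    tvol <- pi * trunk_r^2 * crown_base
    n_trunk <- max(2L, rng(function() stats::rpois(1, tvol * spec$trunk_density)))
    trunk <- rng(function() sample_cylinder(n_trunk, trunk_r, crown_base))
    trunk[, 1] <- trunk[, 1] + cx[i]
    trunk[, 2] <- trunk[, 2] + cy[i]
    pts[[i]] <- rbind(cbind(crown, 1L, i), cbind(trunk, 0L, 0L))
    gt[[i]] <- tibble::tibble(
      instance_id = i, x = cx[i], y = cy[i],
      shape_height = h_shape[i],
      crown_diameter = 2 * r_xy[i],
      crown_volume = vol,
      crown_base = crown_base,
      stage = stages[i]
    )
  }
  m <- do.call(rbind, pts)
  # sparse ground returns across the block footprint
  ext_x <- range(cx) + c(-spec$tree_spacing, spec$tree_spacing) / 2
  ext_y <- range(cy) + c(-spec$row_spacing, spec$row_spacing) / 2
  area <- diff(ext_x) * diff(ext_y)
  n_ground <- rng(function() stats::rpois(1, area * spec$ground_density))
  if (n_ground > 0) {
    gx <- rng(function() stats::runif(n_ground, ext_x[1], ext_x[2]))
    gy <- rng(function() stats::runif(n_ground, ext_y[1], ext_y[2]))
    m <- rbind(m, cbind(gx, gy, 0, 0L, 0L))
  }
  if (spec$noise_sd > 0) {
    m[, 1:3] <- m[, 1:3] + rng(function() stats::rnorm(3 * nrow(m), 0, spec$noise_sd))
  }
  pc <- point_cloud(m[, 1:3, drop = FALSE],
                    semantic = as.integer(m[, 4]),
                    instance = as.integer(m[, 5]))
  truth <- dplyr::bind_rows(gt)
  # realized top height: what a field top-height measurement would record
  tops <- pc |>
    dplyr::filter(.data$instance > 0L) |>
    dplyr::group_by(.data$instance) |>
    dplyr::summarise(height = max(.data$z), .groups = "drop")
  truth <- dplyr::left_join(truth, tops,
                            by = c(instance_id = "instance")) |>
    dplyr::relocate("height", .after = "y")
  ann <- generate_topview_json(pc, truth)
  list(pc = pc, annotations = ann, ground_truth = truth)
}

# Evaluate fn with a private RNG stream so the generator neither depends on
# nor disturbs the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  function(fn) {
    outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(outer)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", outer, globalenv())
    out
  }
}

sample_ellipsoid <- function(n, a, b, c) {
  # rejection from the bounding box; acceptance rate pi/6
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / (pi / 6) * 1.2) + 8
    cand <- matrix(stats::runif(3 * m, -1, 1), ncol = 3)
    keep <- rowSums(cand^2) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  cbind(out[, 1] * a, out[, 2] * b, out[, 3] * c)
}

sample_cylinder <- function(n, r, h) {
  theta <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n))
  cbind(rad * cos(theta), rad * sin(theta), stats::runif(n, 0, h))
}

#' Derive top-view crown polygons from instance labels
#'
#' One implicitly closed polygon per instance: the convex hull of the
#' instance's crown points projected to XY. Alignment is identity (polygon
#' coordinates are point-cloud metres). Instances with fewer than 3 distinct
#' XY positions are skipped with a warning.
#'
#' @param pc A labelled [point_cloud()] with `instance` ids.
#' @param gt Optional ground-truth tibble (unused geometry-wise; retained so
#'   generator pipelines can pipe both through).
#' @return A [crown_annotation_set()].
#' @export
generate_topview_json <- function(pc, gt = NULL) {
  stopifnot(!is.null(pc[["instance"]]))
  ids <- sort(unique(pc[["instance"]][pc[["instance"]] > 0L]))
  polys <- list(); keep_ids <- integer()
  for (id in ids) {
    xy <- unique(as.matrix(pc[pc[["instance"]] == id, c("x", "y")]))
    if (nrow(xy) < 3) {
      warning(sprintf("instance %d has < 3 distinct XY points; skipped", id))
      next
    }
    hull <- grDevices::chull(xy)
    polys[[length(polys) + 1]] <- xy[hull, , drop = FALSE]
    keep_ids <- c(keep_ids, id)
  }
  crown_annotation_set(tibble::tibble(
    instance_id = keep_ids,
    label = rep("crown", length(keep_ids)),
    polygon = polys
  ))
}
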