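#' Extract tree-level structural parameters per instance
#'
#' Standard forest-inventory conventions: height is the instance's maximum
#' z above ground; crown diameter is the equal-area-circle diameter of the
#' XY convex hull of the crown points, `2 * sqrt(A_hull / pi)`; crown
#' volume is the voxel-occupancy volume of the crown points at
#' `voxel_size`. Degenerate instances (a single point, or fewer than 4
#' non-coplanar points for volume) report 0 for the affected quantity with
#' a warning.
#'
#' @param pc A segmented [point_cloud()] with `instance` labels; when a
#'   `semantic` column is present only crown points (`semantic == 1`)
#'   enter the crown diameter/volume.
#' @param ground_z Ground elevation: a constant (default 0, the synthetic
#'   convention) or a per-point vector.
#' @param voxel_size Voxel edge for the occupancy volume (default 0.2 m).
#' @return A tibble: `instance_id`, `n_points`, `height`, `crown_diameter`,
#'   `crown_volume` (metres / cubic metres).
#' @export
extract_metrics <- function(pc, ground_z = 0, voxel_size = 0.2) {
  stopifnot(!is.null(pc[["instance"]]))
  gz <- rep_len(ground_z, nrow(pc))
  ids <- sort(unique(pc[["instance"]][pc[["instance"]] > 0L]))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    idx <- which(pc[["instance"]] == ids[k])
    sub <- pc[idx, ]
    height <- max(sub$z - gz[idx])
    crown <- if (!is.null(sub[["semantic"]])) sub[sub[["semantic"]] == 1L, ] else sub
    if (nrow(crown) == 0) crown <- sub
    xy <- unique(as.matrix(crown[, c("x", "y")]))
    diameter <- if (nrow(xy) < 3) 0 else {
      hull <- grDevices::chull(xy)
      2 * sqrt(polygon_area(xy[hull, , drop = FALSE]) / pi)
    }
    volume <- if (nrow(crown) < 4 || coplanar(crown)) {
      if (nrow(crown) >= 1) warning(sprintf(
        "instance %d has < 4 non-coplanar points; volume reported 0", ids[k]))
      0
    } else {
      nrow(voxelize(crown, voxel_size)$voxel_coords) * voxel_size^3
    }
    out[[k]] <- tibble::tibble(instance_id = ids[k], n_points = length(idx),
                               height = height, crown_diameter = diameter,
                               crown_volume = volume)
  }
  dplyr::bind_rows(out)
}

coplanar <- function(pc) {
  xyz <- unique(as.matrix(pc[, c("x", "y", "z")]))
  if (nrow(xyz) < 4) return(TRUE)
  centered <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sv[3] < 1e-9 * max(sv[1], 1e-12)
}

#' Agreement between predicted and reference tree metrics
#'
#' Joins by `instance_id` and reports, per structural parameter, the
#' coefficient of determination against the identity line
#' (`R^2 = 1 - SS_res / SS_tot`) and the RMSE; per-block breakdowns are
#' added when a `block` column is present in `pred`.
#'
#' @param pred Tibble from [extract_metrics()] (optionally with `block`).
#' @param truth Reference tibble with `instance_id` and the same parameter
#'   columns.
#' @param params Parameter columns to compare.
#' @return An `agreement_report`: tibble with `parameter`, `block`
#'   (`"all"` for the pooled rows), `n`, `r_squared`, `rmse`. Fewer than 2
#'   matched trees yield `NA` for `r_squared`.
#' @export
agreement <- function(pred, truth,
                      params = c("height", "crown_diameter", "crown_volume")) {
  params <- intersect(params, intersect(names(pred), names(truth)))
  joined <- dplyr::inner_join(
    pred, truth, by = "instance_id", suffix = c("_pred", "_true"))
  groups <- list(all = seq_len(nrow(joined)))
  if ("block" %in% names(joined)) {
    groups <- c(groups, split(seq_len(nrow(joined)), joined$block))
  }
  rows <- list()
  for (bn in names(groups)) {
    idx <- groups[[bn]]
    for (p in params) {
      yp <- joined[[paste0(p, "_pred")]][idx]
      yt <- joined[[paste0(p, "_true")]][idx]
      n <- length(idx)
      if (n < 2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          parameter = p, block = bn, n = n, r_squared = NA_real_,
          rmse = if (n == 1) abs(yp - yt) else NA_real_)
        next
      }
      ss_res <- sum((yp - yt)^2)
      ss_tot <- sum((yt - mean(yt))^2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = p, block = bn, n = n,
        r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
        rmse = sqrt(ss_res / n))
    }
  }
  structure(list(table = dplyr::bind_rows(rows), data = joined,
                 params = params),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("# Structural parameter agreement\n")
  print(x$table[x$table$block == "all", ])
  invisible(x)
}
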