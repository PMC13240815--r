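#' Build a point cloud tibble
#'
#' The universal carrier of the package: a tibble with one row per LiDAR
#' return and columns `x`, `y`, `z` (metres), plus optional per-point
#' `semantic` labels (0 = background, 1 = crown), `instance` identifiers
#' (positive integers; 0 is reserved for background / unassigned) and
#' `intensity`. All downstream stages accept and return this shape so calls
#' chain with the pipe.
#'
#' @param coords A data frame or matrix with columns/axes x, y, z (metres).
#' @param semantic Optional integer vector in \{0, 1\}.
#' @param instance Optional vector of non-negative integers; every point with
#'   `instance > 0` must have `semantic = 1` when both are supplied.
#' @param intensity Optional numeric vector.
#' @return A `point_cloud` tibble (subclass of `tbl_df`).
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), runif(10)))
#' @export
point_cloud <- function(coords, semantic = NULL, instance = NULL,
                        intensity = NULL) {
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) == 3)
    coords <- tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  coords <- tibble::as_tibble(coords)
  if (!all(c("x", "y", "z") %in% names(coords))) {
    stop("coords must provide columns x, y, z", call. = FALSE)
  }
  pc <- coords[, intersect(c("x", "y", "z", "semantic", "instance", "intensity"),
                           names(coords))]
  if (!is.null(semantic))  pc[["semantic"]]  <- as.integer(semantic)
  if (!is.null(instance))  pc[["instance"]]  <- as.integer(instance)
  if (!is.null(intensity)) pc[["intensity"]] <- as.double(intensity)
  class(pc) <- c("point_cloud", class(tibble::tibble()))
  validate_point_cloud(pc)
}

#' Validate point-cloud invariants
#'
#' Checks finiteness of coordinates, label domains, and the coupling rule
#' that instance-labelled points are crown points. Called by [point_cloud()];
#' exported so readers of foreign files can re-validate.
#'
#' @param pc A `point_cloud` tibble.
#' @return `pc`, invisibly unchanged, or an error.
#' @export
validate_point_cloud <- function(pc) {
  if (nrow(pc) < 1) stop("point cloud must contain at least one point", call. = FALSE)
  xyz <- as.matrix(pc[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!stats::complete.cases(is.finite(xyz)) | rowSums(!is.finite(xyz)) > 0)[1]
    stop(sprintf("non-finite coordinate at point %d", bad), call. = FALSE)
  }
  if (!is.null(pc[["semantic"]]) && !all(pc[["semantic"]] %in% c(0L, 1L))) {
    stop("semantic labels must be 0 (background) or 1 (crown)", call. = FALSE)
  }
  if (!is.null(pc[["instance"]])) {
    if (any(pc[["instance"]] < 0L)) stop("instance ids must be non-negative", call. = FALSE)
    if (!is.null(pc[["semantic"]]) && any(pc[["instance"]] > 0L & pc[["semantic"]] != 1L)) {
      stop("points with instance > 0 must have semantic = 1", call. = FALSE)
    }
  }
  invisible(pc)
}

#' Compact instance identifiers to a contiguous 1..M set
#'
#' Remaps the positive instance ids of a point cloud onto `1..M` preserving
#' their numeric order; 0 (background) is left untouched.
#'
#' @param pc A `point_cloud` tibble with an `instance` column.
#' @return The point cloud with compacted ids.
#' @export
compact_instances <- function(pc) {
  stopifnot(!is.null(pc[["instance"]]))
  ids <- sort(unique(pc[["instance"]][pc[["instance"]] > 0L]))
  pc[["instance"]] <- ifelse(pc[["instance"]] > 0L,
                        match(pc[["instance"]], ids),
                        0L)
  pc[["instance"]] <- as.integer(pc[["instance"]])
  pc
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("# Point cloud: %d points%s%s\n", nrow(x),
              if (!is.null(x[["semantic"]])) sprintf(", %d crown", sum(x[["semantic"]] == 1L)) else "",
              if (!is.null(x[["instance"]])) sprintf(", %d instances", length(unique(x[["instance"]][x[["instance"]] > 0L]))) else ""))
  NextMethod()
}
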