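#' Construct a crown annotation set
#'
#' The 2D modality: one closed polygon per annotated crown in top-view image
#' coordinates, with an affine alignment mapping image XY onto point-cloud
#' XY. The on-disk form is a LabelMe-style JSON file (see
#' [read_crown_annotations()]); this constructor holds the parsed form.
#'
#' @param polygons A tibble with columns `instance_id` (unique positive
#'   integers), `label` (character, `"crown"` or `"background"`), and
#'   `polygon` (list of V x 2 numeric matrices; polygons are implicitly
#'   closed, the first vertex need not be repeated).
#' @param alignment 3 x 3 affine matrix mapping homogeneous image XY to
#'   point-cloud XY; identity by default. Must be invertible.
#' @param region_bounds Optional `c(xmin, xmax, ymin, ymax)` extent of the
#'   annotated block.
#' @return A `crown_annotation_set` object.
#' @export
crown_annotation_set <- function(polygons = NULL, alignment = diag(3),
                                 region_bounds = NULL) {
  if (is.null(polygons)) {
    polygons <- tibble::tibble(instance_id = integer(), label = character(),
                               polygon = list())
  }
  polygons <- tibble::as_tibble(polygons)
  stopifnot(all(c("instance_id", "label", "polygon") %in% names(polygons)))
  if (anyDuplicated(polygons$instance_id)) {
    stop("duplicate instance_id in annotation set", call. = FALSE)
  }
  for (i in seq_len(nrow(polygons))) {
    poly <- polygons$polygon[[i]]
    poly <- drop_closing_vertex(poly)
    if (nrow(poly) < 3) {
      stop(sprintf("polygon for instance %d has fewer than 3 vertices",
                   polygons$instance_id[i]), call. = FALSE)
    }
    polygons$polygon[[i]] <- poly
  }
  if (abs(det(alignment)) < 1e-12) stop("alignment matrix is singular", call. = FALSE)
  structure(list(polygons = polygons, alignment = alignment,
                 region_bounds = region_bounds, schema_version = "1.0"),
            class = "crown_annotation_set")
}

drop_closing_vertex <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  poly
}

#' @export
print.crown_annotation_set <- function(x, ...) {
  cat(sprintf("# Crown annotation set: %d polygons (schema %s)\n",
              nrow(x$polygons), x$schema_version))
  invisible(x)
}

#' Read crown annotations from a LabelMe-style JSON file
#'
#' The accepted schema (versioned with this package) is
#' `{"shapes": [{"label": "tree_1", "points": [[x, y], ...],
#' "shape_type": "polygon", "group_id": 1}, ...], "alignment": {"matrix":
#' [a, b, tx, c, d, ty]}}`. Instance ids are taken from `group_id` when
#' present, else parsed from a trailing integer in the label, else assigned
#' sequentially. The alignment defaults to identity when absent. A file with
#' zero shapes parses to an empty set.
#'
#' @param path Path to the JSON file.
#' @return A [crown_annotation_set()].
#' @export
read_crown_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shapes <- doc$shapes %||% list()
  ids <- integer(length(shapes)); labels <- character(length(shapes))
  polys <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(drop_closing_vertex(pts)) < 3) {
      stop(sprintf("shape %d is not a valid closed polygon (need >= 3 vertices)", i),
           call. = FALSE)
    }
    polys[[i]] <- pts
    labels[i] <- if (grepl("background", sh$label %||% "")) "background" else "crown"
    id <- sh$group_id
    if (is.null(id)) {
      m <- regmatches(sh$label %||% "", regexpr("[0-9]+$", sh$label %||% ""))
      id <- if (length(m)) as.integer(m) else NA_integer_
    }
    ids[i] <- as.integer(id)
  }
  if (anyNA(ids)) ids[is.na(ids)] <- setdiff(seq_len(length(ids) * 2L), ids)[seq_len(sum(is.na(ids)))]
  align <- diag(3)
  if (!is.null(doc$alignment$matrix)) {
    v <- as.numeric(unlist(doc$alignment$matrix))
    align <- rbind(matrix(v, nrow = 2, byrow = TRUE), c(0, 0, 1))
  }
  bounds <- if (!is.null(doc$region_bounds)) as.numeric(unlist(doc$region_bounds))
  crown_annotation_set(
    tibble::tibble(instance_id = ids, label = labels, polygon = polys),
    alignment = align, region_bounds = bounds
  )
}

#' Write crown annotations to LabelMe-style JSON
#'
#' @param ann A [crown_annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crown_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "crown_annotation_set"))
  shapes <- purrr::pmap(ann$polygons, function(instance_id, label, polygon) {
    list(label = sprintf("tree_%d", instance_id),
         group_id = instance_id,
         shape_type = "polygon",
         points = unname(apply(polygon, 1, as.list, simplify = FALSE)))
  })
  doc <- list(
    version = ann$schema_version,
    shapes = shapes,
    alignment = list(matrix = as.numeric(t(ann$alignment[1:2, ])))
  )
  if (!is.null(ann$region_bounds)) doc$region_bounds <- ann$region_bounds
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map annotation polygons into point-cloud XY coordinates
#'
#' Applies the set's affine alignment to every polygon.
#'
#' @param ann A [crown_annotation_set()].
#' @return The set with transformed polygons and identity alignment.
#' @export
align_annotations <- function(ann) {
  A <- ann$alignment
  ann$polygons$polygon <- purrr::map(ann$polygons$polygon, function(p) {
    h <- cbind(p, 1) %*% t(A)
    h[, 1:2, drop = FALSE]
  })
  ann$alignment <- diag(3)
  ann
}

# Shoelace area of an implicitly closed polygon
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Even-odd rule point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  parity <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    parity <- xor(parity, cross)
    boundary <- boundary |
      (abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi)) < 1e-9 &
         px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
         py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9)
    j <- i
  }
  parity | boundary
}
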