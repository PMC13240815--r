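#' Read a point cloud from disk
#'
#' Supported formats: whitespace-delimited `xyz` (columns
#' `x y z [semantic] [instance]`), PLY (ascii and binary little-endian, with
#' optional per-vertex `intensity`, `semantic` and `instance` properties) and
#' LAS 1.2 point format 0. For LAS the semantic label travels in the standard
#' `classification` field and the instance id in `point source ID` (the LAS
#' Extra Bytes mechanism is deliberately not used). LAZ is not supported.
#'
#' @param path Path to the file.
#' @param format One of `"xyz"`, `"ply"`, `"las"`; inferred from the file
#'   extension when omitted.
#' @return A [point_cloud()] tibble.
#' @export
read_pointcloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    xyz = read_xyz(path),
    ply = read_ply(path),
    las = read_las(path),
    stop("unsupported point-cloud format: ", format, call. = FALSE)
  )
}

#' Write a point cloud to disk
#'
#' @param pc A [point_cloud()] tibble.
#' @param path Output path.
#' @param format `"xyz"`, `"ply"` or `"las"`; inferred from the extension
#'   when omitted.
#' @param binary For PLY, write `binary_little_endian` instead of ascii.
#'   xyz and ascii PLY round-trip coordinates bit-exactly; LAS quantizes to a
#'   1 mm grid.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(pc, path, format = NULL, binary = FALSE) {
  validate_point_cloud(pc)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    xyz = write_xyz(pc, path),
    ply = write_ply(pc, path, binary = binary),
    las = write_las(pc, path),
    stop("unsupported point-cloud format: ", format, call. = FALSE)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || identical(a, "")) b else a

# ---- xyz ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty xyz file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (length(unique(nf)) != 1L || !unique(nf) %in% 3:5) {
    bad <- which(nf != nf[1] | !nf %in% 3:5)[1]
    stop(sprintf("malformed xyz record at line %d (expected 3-5 fields)", bad),
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = nf[1], byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("malformed xyz record at line %d (non-numeric field)", bad),
         call. = FALSE)
  }
  point_cloud(m[, 1:3, drop = FALSE],
              semantic = if (nf[1] >= 4) as.integer(m[, 4]),
              instance = if (nf[1] >= 5) as.integer(m[, 5]))
}

write_xyz <- function(pc, path) {
  cols <- list(fmt_dbl(pc$x), fmt_dbl(pc$y), fmt_dbl(pc$z))
  if (!is.null(pc[["semantic"]])) cols <- c(cols, list(as.character(pc[["semantic"]])))
  if (!is.null(pc[["instance"]])) {
    if (is.null(pc[["semantic"]])) stop("xyz dialect stores instance only together with semantic", call. = FALSE)
    cols <- c(cols, list(as.character(pc[["instance"]])))
  }
  writeLines(do.call(paste, cols), path)
}

# %.17g is enough digits that read-back reproduces the double bit-exactly
fmt_dbl <- function(v) formatC(v, format = "g", digits = 17)

# ---- PLY ------------------------------------------------------------------

ply_types <- list(
  char = c(1, "int"), int8 = c(1, "int"), uchar = c(1, "int"), uint8 = c(1, "int"),
  short = c(2, "int"), int16 = c(2, "int"), ushort = c(2, "int"), uint16 = c(2, "int"),
  int = c(4, "int"), int32 = c(4, "int"), uint = c(4, "int"), uint32 = c(4, "int"),
  float = c(4, "double"), float32 = c(4, "double"),
  double = c(8, "double"), float64 = c(8, "double")
)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL; n_vertex <- NULL; props <- list(); in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("PLY header truncated", call. = FALSE)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
      else if (!is.null(n_vertex)) break  # only trailing non-vertex elements tolerated
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("list properties on vertices are unsupported", call. = FALSE)
      props[[tok[3]]] <- tok[2]
    } else if (tok[1] == "end_header") break
  }
  if (is.null(n_vertex)) stop("PLY file has no vertex element", call. = FALSE)
  unknown <- setdiff(unlist(props), names(ply_types))
  if (length(unknown)) stop("unsupported PLY property type: ", unknown[1], call. = FALSE)
  cols <-
    if (identical(fmt, "ascii")) {
      read_ply_ascii(con, n_vertex, props)
    } else if (identical(fmt, "binary_little_endian")) {
      read_ply_binary(con, n_vertex, props)
    } else stop("unsupported PLY format: ", fmt, call. = FALSE)
  if (!all(c("x", "y", "z") %in% names(cols))) {
    stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
  }
  point_cloud(tibble::tibble(x = cols$x, y = cols$y, z = cols$z),
              semantic = cols$semantic, instance = cols$instance,
              intensity = cols$intensity)
}

read_ply_ascii <- function(con, n, props) {
  lines <- readLines(con, n = n)
  if (length(lines) < n) stop("PLY vertex data truncated", call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(toks) != length(props))) {
    bad <- which(lengths(toks) != length(props))[1]
    stop(sprintf("malformed PLY vertex record %d", bad), call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(toks)), ncol = length(props), byrow = TRUE)
  stats::setNames(lapply(seq_along(props), function(j) m[, j]), names(props))
}

read_ply_binary <- function(con, n, props) {
  sizes <- vapply(props, function(t) as.integer(ply_types[[t]][1]), 1L)
  rec <- sum(sizes)
  raw <- readBin(con, what = "raw", n = rec * n)
  if (length(raw) < rec * n) stop("PLY vertex data truncated", call. = FALSE)
  rawm <- matrix(raw, nrow = rec)
  offset <- 0L
  out <- list()
  for (j in seq_along(props)) {
    sz <- sizes[j]; ty <- props[[j]]
    chunk <- as.vector(rawm[(offset + 1):(offset + sz), , drop = FALSE])
    what <- ply_types[[ty]][2]
    signed <- !grepl("^u", ty)
    out[[names(props)[j]]] <- readBin(chunk, what = what, n = n, size = sz,
                                      signed = if (sz < 4) signed else TRUE,
                                      endian = "little")
    offset <- offset + sz
  }
  out
}

write_ply <- function(pc, path, binary = FALSE) {
  props <- list(x = "double", y = "double", z = "double")
  if (!is.null(pc[["intensity"]])) props$intensity <- "double"
  if (!is.null(pc[["semantic"]]))  props$semantic <- "uchar"
  if (!is.null(pc[["instance"]]))  props$instance <- "int"
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment treeparse3d point cloud",
    sprintf("element vertex %d", nrow(pc)),
    sprintf("property %s %s", unlist(props), names(props)),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (!binary) {
    cols <- lapply(names(props), function(nm) {
      if (props[[nm]] == "double") fmt_dbl(pc[[nm]]) else as.character(pc[[nm]])
    })
    writeLines(do.call(paste, cols), con)
  } else {
    n <- nrow(pc)
    sizes <- vapply(props, function(t) as.integer(ply_types[[t]][1]), 1L)
    rawm <- matrix(as.raw(0), nrow = sum(sizes), ncol = n)
    offset <- 0L
    for (j in seq_along(props)) {
      nm <- names(props)[j]; sz <- sizes[j]
      bytes <- if (props[[nm]] == "double") {
        writeBin(as.double(pc[[nm]]), raw(), size = 8, endian = "little")
      } else if (sz == 1) {
        as.raw(pc[[nm]])
      } else {
        writeBin(as.integer(pc[[nm]]), raw(), size = sz, endian = "little")
      }
      rawm[(offset + 1):(offset + sz), ] <- matrix(bytes, nrow = sz)
      offset <- offset + sz
    }
    writeBin(as.vector(rawm), con)
  }
}

# ---- LAS 1.2, point data record format 0 ----------------------------------

write_las <- function(pc, path) {
  n <- nrow(pc)
  scale <- 0.001
  off <- vapply(pc[, c("x", "y", "z")], min, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size, type = "integer") writeBin(x, con, size = size, endian = "little")
  writeChar("LASF", con, nchars = 4, eos = NULL)
  w(0L, 2); w(0L, 2)                     # file source id, global encoding
  writeBin(as.raw(rep(0, 16)), con)      # GUID
  writeBin(as.raw(c(1, 2)), con)         # version 1.2
  writeBin(as.raw(rep(0, 64)), con)      # system id + software
  w(1L, 2); w(2026L, 2)                  # day, year
  w(227L, 2)                             # header size
  w(227L, 4)                             # offset to point data
  w(0L, 4)                               # number of VLRs
  writeBin(as.raw(0), con)               # point data format 0
  w(20L, 2)                              # record length
  w(n, 4)
  for (i in 1:5) w(if (i == 1) n else 0L, 4)
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(as.double(off), con, size = 8, endian = "little")
  writeBin(as.double(c(max(pc$x), min(pc$x), max(pc$y), min(pc$y),
                       max(pc$z), min(pc$z))), con, size = 8, endian = "little")
  rawm <- matrix(as.raw(0), nrow = 20, ncol = n)
  put <- function(rows, bytes) rawm[rows, ] <<- matrix(bytes, nrow = length(rows))
  put(1:4,   writeBin(as.integer(round((pc$x - off[1]) / scale)), raw(), size = 4, endian = "little"))
  put(5:8,   writeBin(as.integer(round((pc$y - off[2]) / scale)), raw(), size = 4, endian = "little"))
  put(9:12,  writeBin(as.integer(round((pc$z - off[3]) / scale)), raw(), size = 4, endian = "little"))
  inten <- as.integer(pmin(pmax(round(pc[["intensity"]] %||% rep(0, n)), 0), 65535))
  put(13:14, writeBin(inten, raw(), size = 2, endian = "little"))
  put(15, as.raw(rep(0x09, n)))                       # return 1 of 1
  put(16, as.raw(pc[["semantic"]] %||% rep(0L, n)))        # classification
  put(17, as.raw(rep(0, n)))                          # scan angle
  put(18, as.raw(rep(0, n)))                          # user data
  put(19:20, writeBin(as.integer(pc[["instance"]] %||% rep(0L, n)), raw(), size = 2, endian = "little"))
  writeBin(as.vector(rawm), con)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  readBin(con, "raw", n = 20)            # through GUID
  ver <- readBin(con, "raw", n = 2)
  readBin(con, "raw", n = 68)            # system id .. year
  readBin(con, "integer", size = 2, endian = "little", signed = FALSE)  # header size
  offset_to_points <- readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 4, endian = "little")  # n VLR
  pdrf <- as.integer(readBin(con, "raw", n = 1))
  if (pdrf != 0L) stop("only LAS point data format 0 is supported", call. = FALSE)
  reclen <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
  n <- readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 4, n = 5, endian = "little")
  scale <- readBin(con, "double", n = 3, size = 8, endian = "little")
  off <- readBin(con, "double", n = 3, size = 8, endian = "little")
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = reclen * n)
  if (length(raw) < reclen * n) stop("LAS point data truncated", call. = FALSE)
  rawm <- matrix(raw, nrow = reclen)
  geti32 <- function(rows) readBin(as.vector(rawm[rows, , drop = FALSE]),
                                   "integer", n = n, size = 4, endian = "little")
  x <- geti32(1:4) * scale[1] + off[1]
  y <- geti32(5:8) * scale[2] + off[2]
  z <- geti32(9:12) * scale[3] + off[3]
  inten <- readBin(as.vector(rawm[13:14, , drop = FALSE]), "integer", n = n,
                   size = 2, signed = FALSE, endian = "little")
  cls <- as.integer(rawm[16, ])
  psid <- readBin(as.vector(rawm[19:20, , drop = FALSE]), "integer", n = n,
                  size = 2, signed = FALSE, endian = "little")
  point_cloud(tibble::tibble(x = x, y = y, z = z),
              semantic = if (any(cls > 0)) as.integer(cls > 0) else NULL,
              instance = if (any(psid > 0)) psid else NULL,
              intensity = if (any(inten > 0)) as.double(inten) else NULL)
}

# ---- normalization --------------------------------------------------------

#' Min-max normalize coordinates to the unit cube
#'
#' Maps each axis of a block to `[0, 1]` (min to 0, max to 1). A degenerate
#' axis (zero extent) maps to 0.5. Normalization is per block, not global:
#' the trilinear fusion weights downstream require coordinates inside the
#' unit cube of the current block.
#'
#' @param pc A [point_cloud()] tibble.
#' @return A list with `pc` (normalized point cloud) and `record` (a
#'   `normalization_record` carrying the inverse transform).
#' @seealso [denormalize_coords()]
#' @export
normalize_coords <- function(pc) {
  validate_point_cloud(pc)
  mins <- vapply(pc[, c("x", "y", "z")], min, 0)
  maxs <- vapply(pc[, c("x", "y", "z")], max, 0)
  ranges <- maxs - mins
  degen <- ranges == 0
  out <- pc
  for (j in seq_along(c("x", "y", "z"))) {
    ax <- c("x", "y", "z")[j]
    out[[ax]] <- if (degen[j]) rep(0.5, nrow(pc)) else (pc[[ax]] - mins[j]) / ranges[j]
  }
  record <- structure(list(mins = mins, ranges = ranges, degenerate = degen),
                      class = "normalization_record")
  list(pc = out, record = record)
}

#' Invert a coordinate normalization
#'
#' @param pc Normalized point cloud.
#' @param record The `normalization_record` from [normalize_coords()].
#' @return The point cloud in original coordinates.
#' @export
denormalize_coords <- function(pc, record) {
  stopifnot(inherits(record, "normalization_record"))
  out <- pc
  for (j in seq_along(c("x", "y", "z"))) {
    ax <- c("x", "y", "z")[j]
    out[[ax]] <- if (record$degenerate[j]) rep(record$mins[j], nrow(pc))
                 else pc[[ax]] * record$ranges[j] + record$mins[j]
  }
  out
}
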