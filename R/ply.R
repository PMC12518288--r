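# PLY (Stanford polygon format) I/O restricted to what the pipeline needs:
# an element "vertex" with float x,y,z, optional uchar red,green,blue and an
# optional integer "label" property. Both ASCII and binary_little_endian are
# read; ASCII is the default on write for diffability.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply"))
    sricp_stop("not a PLY file: missing 'ply' magic line", "sricp_ply_header")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      sricp_stop("malformed PLY header: missing end_header", "sricp_ply_header")
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "end_header") break
    if (tok[1] == "format") {
      if (!tok[2] %in% c("ascii", "binary_little_endian"))
        sricp_stop(sprintf("unsupported PLY format '%s'", tok[2]),
                   "sricp_ply_header")
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(0), types = character(0))
      elements[[tok[2]]] <- cur
    } else if (tok[1] == "property") {
      if (is.null(cur))
        sricp_stop("malformed PLY header: property before element",
                   "sricp_ply_header")
      if (tok[2] == "list") {
        elements[[cur$name]]$list <- TRUE
        elements[[cur$name]]$props <- c(elements[[cur$name]]$props, tok[5])
        elements[[cur$name]]$types <- c(elements[[cur$name]]$types, "list")
      } else {
        if (!tok[2] %in% names(.ply_type_size))
          sricp_stop(sprintf("unknown PLY property type '%s'", tok[2]),
                     "sricp_ply_header")
        elements[[cur$name]]$props <- c(elements[[cur$name]]$props, tok[3])
        elements[[cur$name]]$types <- c(elements[[cur$name]]$types, tok[2])
      }
      cur <- elements[[cur$name]]
    }
  }
  if (is.null(fmt))
    sricp_stop("malformed PLY header: no format line", "sricp_ply_header")
  list(format = fmt, elements = elements)
}

#' Read a colored point cloud from a PLY file
#'
#' Reads the `vertex` element of an ASCII or binary-little-endian PLY file.
#' Properties `x`, `y`, `z` are required; `red`, `green`, `blue` default to
#' 255 when absent and an integer `label` property, when present, populates
#' the cloud's labels (absent = all -1). Point order is preserved.
#'
#' @param path path to a PLY file
#' @return a [point_cloud()]
#' @export
read_ply <- function(path) {
  if (!file.exists(path))
    sricp_stop(sprintf("PLY file does not exist: '%s'", path),
               "sricp_ply_missing_file")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .ply_read_header(con)
  vtx <- hdr$elements[["vertex"]]
  if (is.null(vtx))
    sricp_stop("PLY file has no vertex element", "sricp_ply_header")
  if (!all(c("x", "y", "z") %in% vtx$props))
    sricp_stop("PLY vertex element lacks x,y,z coordinate properties",
               "sricp_ply_missing_property")
  pre <- names(hdr$elements)
  if (match("vertex", pre) != 1L)
    sricp_stop("PLY files with elements before 'vertex' are unsupported",
               "sricp_ply_header")
  n <- vtx$count
  if (hdr$format == "ascii") {
    cols <- length(vtx$props)
    vals <- scan(con, what = numeric(), n = n * cols, quiet = TRUE)
    if (length(vals) < n * cols)
      sricp_stop("PLY vertex data truncated", "sricp_ply_data")
    m <- matrix(vals, ncol = cols, byrow = TRUE)
    colnames(m) <- vtx$props
  } else {
    if (any(vtx$types == "list"))
      sricp_stop("list properties on binary vertex elements are unsupported",
                 "sricp_ply_header")
    sizes <- .ply_type_size[vtx$types]
    rowsize <- sum(sizes)
    raw <- readBin(con, "raw", n = n * rowsize)
    if (length(raw) < n * rowsize)
      sricp_stop("PLY vertex data truncated", "sricp_ply_data")
    rawm <- matrix(raw, nrow = rowsize)
    m <- matrix(0, n, length(vtx$props), dimnames = list(NULL, vtx$props))
    off <- 0L
    for (j in seq_along(vtx$props)) {
      ty <- vtx$types[j]
      sz <- sizes[[j]]
      bytes <- as.vector(rawm[off + seq_len(sz), , drop = FALSE])
      m[, j] <- switch(ty,
        float = , float32 = readBin(bytes, "double", n = n, size = 4L,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "double", n = n, size = 8L,
                                     endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = n,
                                             size = 1L, signed = FALSE,
                                             endian = "little")),
        char = , int8 = as.numeric(readBin(bytes, "integer", n = n, size = 1L,
                                           signed = TRUE, endian = "little")),
        ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = n,
                                               size = 2L, signed = FALSE,
                                               endian = "little")),
        short = , int16 = as.numeric(readBin(bytes, "integer", n = n,
                                             size = 2L, signed = TRUE,
                                             endian = "little")),
        int = , int32 = , uint = , uint32 =
          as.numeric(readBin(bytes, "integer", n = n, size = 4L,
                             endian = "little")))
      off <- off + sz
    }
  }
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  cols <- if (all(c("red", "green", "blue") %in% vtx$props))
    round(m[, c("red", "green", "blue"), drop = FALSE]) else NULL
  labels <- if ("label" %in% vtx$props) as.integer(m[, "label"]) else NULL
  point_cloud(pts, cols, labels)
}

#' Write a point cloud to a PLY file
#'
#' Writes an `element vertex` with float `x,y,z`, uchar `red,green,blue` and,
#' if any label differs from -1, an int `label` property. Round-tripping
#' through [read_ply()] preserves colors and labels exactly and coordinates to
#' 32-bit float precision.
#'
#' @param cloud a [point_cloud()]
#' @param path output path
#' @param binary write binary_little_endian instead of ASCII (default FALSE)
#' @return `path`, invisibly
#' @export
write_ply <- function(cloud, path, binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  with_labels <- n > 0L && any(cloud$labels != -1L)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           if (with_labels) "property int label",
           "end_header")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) sricp_stop(
                    sprintf("cannot open '%s' for writing", path),
                    "sricp_ply_unwritable"))
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    sizes <- c(4L, 4L, 4L, 1L, 1L, 1L, if (with_labels) 4L)
    rowsize <- sum(sizes)
    rawm <- matrix(as.raw(0), rowsize, n)
    off <- 0L
    for (j in 1:3) {
      rawm[off + 1:4, ] <- matrix(
        writeBin(as.vector(cloud$points[, j]), raw(), size = 4L,
                 endian = "little"), 4L)
      off <- off + 4L
    }
    for (j in 1:3) {
      rawm[off + 1L, ] <- as.raw(cloud$colors[, j])
      off <- off + 1L
    }
    if (with_labels)
      rawm[off + 1:4, ] <- matrix(
        writeBin(cloud$labels, raw(), size = 4L, endian = "little"), 4L)
    writeBin(as.vector(rawm), con)
  } else {
    # print coordinates with enough digits for exact float32 round-trip
    body <- sprintf("%.9g %.9g %.9g %d %d %d",
                    cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                    cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3])
    if (with_labels) body <- paste(body, cloud$labels)
    writeLines(body, con)
  }
  invisible(path)
}
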