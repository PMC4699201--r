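#' Triangulated surface
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_surface` object.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as_point_matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3)
    stop_lheart("lheart_parameter_error", "triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop_lheart("lheart_parameter_error", "triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

surface_edges <- function(surface) {
  f <- surface$triangles
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

edge_key <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# edges not shared by exactly two triangles (as a two-column index matrix)
bad_edges <- function(surface) {
  e <- surface_edges(surface)
  k <- edge_key(e)
  tab <- table(k)
  bad <- names(tab)[tab != 2]
  if (length(bad) == 0) return(matrix(0L, 0, 2))
  m <- do.call(rbind, strsplit(bad, " "))
  storage.mode(m) <- "integer"
  m
}

#' Surface integrity checks
#'
#' A surface is watertight when every edge is shared by exactly two
#' triangles and the two incident triangles traverse it in opposite
#' directions (consistent orientation).
#'
#' @param surface a [tri_surface()].
#' @return `is_watertight`: logical. `euler_characteristic`: V - E + F.
#'   `surface_volume`: enclosed signed volume in mm^3 (positive for outward
#'   orientation). `surface_area`: total triangle area in mm^2.
#' @export
is_watertight <- function(surface) {
  if (nrow(surface$triangles) == 0) return(FALSE)
  e <- surface_edges(surface)
  k <- edge_key(e)
  if (any(table(k) != 2)) return(FALSE)
  # consistent orientation: each directed edge appears exactly once
  !any(duplicated(paste(e[, 1], e[, 2])))
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(surface) {
  e <- unique(edge_key(surface_edges(surface)))
  nrow(surface$vertices) - length(e) + nrow(surface$triangles)
}

#' @rdname is_watertight
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' @rdname is_watertight
#' @export
surface_area <- function(surface) {
  sum(triangle_areas(surface$vertices, surface$triangles))
}

triangle_areas <- function(v, f) {
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

check_watertight <- function(surface, who) {
  be <- bad_edges(surface)
  if (nrow(be) > 0)
    stop_lheart("lheart_nonmanifold", sprintf(
      "%s requires a watertight surface; offending edges: %s",
      who, paste(apply(head(be, 10), 1, paste, collapse = "-"),
                 collapse = ", ")))
  if (!is_watertight(surface))
    stop_lheart("lheart_nonmanifold",
                sprintf("%s requires a consistently oriented surface", who))
  invisible(TRUE)
}

#' Write / read a triangle mesh
#'
#' Supported formats: PLY (ASCII or binary little-endian), OFF, and ASCII
#' STL. Writing refuses non-watertight surfaces and reports the offending
#' edges. STL stores no connectivity, so `read_mesh` re-welds exactly
#' coincident vertices when reading STL.
#'
#' @param surface a [tri_surface()].
#' @param path output file; the format is chosen by `format`, defaulting to
#'   the file extension.
#' @param format `"ply"`, `"off"` or `"stl"`.
#' @param binary logical, write binary PLY instead of ASCII.
#' @export
write_mesh <- function(surface, path,
                       format = c("auto", "ply", "off", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "off", "stl"))
    stop_lheart("lheart_parameter_error",
                sprintf("unsupported mesh format '%s'", format))
  check_watertight(surface, "write_mesh")
  v <- surface$vertices
  f <- surface$triangles
  if (format == "ply") {
    hdr <- c("ply",
             if (binary) "format binary_little_endian 1.0"
             else "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      writeBin(as.vector(t(v)), con, size = 8, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
      }
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(hdr, con)
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
    }
  } else if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {  # ascii stl
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid lheart", con)
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
      n <- c((b[2]-a[2])*(c3[3]-a[3]) - (b[3]-a[3])*(c3[2]-a[2]),
             (b[3]-a[3])*(c3[1]-a[1]) - (b[1]-a[1])*(c3[3]-a[3]),
             (b[1]-a[1])*(c3[2]-a[2]) - (b[2]-a[2])*(c3[1]-a[1]))
      nn <- vnorm(n); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.17g %.17g %.17g",
                           c(a[1], b[1], c3[1]), c(a[2], b[2], c3[2]),
                           c(a[3], b[3], c3[3])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid lheart", con)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = c("auto", "ply", "off", "stl")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (format == "ply") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character()
    repeat {
      ln <- readLines(con, 1)
      hdr <- c(hdr, ln)
      if (identical(ln, "end_header")) break
      if (length(hdr) > 100)
        stop_lheart("lheart_parse_error", "malformed PLY header")
    }
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                     hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face",
                                                   hdr, value = TRUE)))
    binary <- any(grepl("binary_little_endian", hdr))
    if (binary) {
      v <- matrix(readBin(con, "double", nv * 3, size = 8,
                          endian = "little"), nv, 3, byrow = TRUE)
      f <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        readBin(con, "raw", 1)
        f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
      }
    } else {
      txt <- readLines(con)
      v <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]), "\\s+"),
                                 as.numeric))
      fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
      f <- do.call(rbind, lapply(fl, function(x) as.integer(x[2:4]) + 1L))
    }
    return(tri_surface(v, f))
  }
  if (format == "off") {
    txt <- readLines(path)
    txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
    if (trimws(txt[1]) != "OFF")
      stop_lheart("lheart_parse_error", "not an OFF file")
    counts <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    v <- do.call(rbind, lapply(strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+"),
                               as.numeric))
    fl <- strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+")
    f <- do.call(rbind, lapply(fl, function(x) as.integer(x[2:4]) + 1L))
    return(tri_surface(v, f))
  }
  if (format == "stl") {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    if (nrow(coords) %% 3 != 0)
      stop_lheart("lheart_parse_error", "malformed STL facet list")
    key <- apply(coords, 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    v <- coords[!duplicated(key), , drop = FALSE]
    f <- matrix(uid, ncol = 3, byrow = TRUE)
    return(tri_surface(v, f))
  }
  stop_lheart("lheart_parameter_error",
              sprintf("unsupported mesh format '%s'", format))
}
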