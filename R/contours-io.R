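#' Planar labelled contour
#'
#' An ordered list of (u, v) pixel coordinates delineated on one imaging
#' plane, labelled with the anatomical structure it bounds. Contours on
#' slices through the ventricular in/outflow junction, where left ventricle,
#' left atrium and aorta cannot be separated, carry the `MERGED` label.
#'
#' @param points numeric matrix, one (u, v) pixel coordinate per row.
#'   Closed contours are stored without repeating the first point.
#' @param label one of `"LV"`, `"LA"`, `"AO"`, `"MERGED"`.
#' @param plane_id id of the plane the contour was drawn on.
#' @param closed logical; closed contours need at least 3 points.
#' @return A `contour2d` object.
#' @export
contour2d <- function(points, label = c("LV", "LA", "AO", "MERGED"),
                      plane_id = "plane", closed = TRUE) {
  label <- match.arg(label)
  points <- as_point_matrix(points, 2, "contour points")
  n <- nrow(points)
  if (n >= 2) {
    # drop the conventional repeated closing point, then forbid duplicates
    if (closed && all(points[1, ] == points[n, ])) {
      points <- points[-n, , drop = FALSE]
      n <- n - 1
    }
    dup <- rowSums((points - points[c(2:n, 1), , drop = FALSE])^2) == 0
    if (closed && any(dup) || !closed && any(dup[-n]))
      stop_lheart("lheart_parameter_error",
                  "contour has identical consecutive points")
  }
  if (closed && n < 3)
    stop_lheart("lheart_parameter_error",
                sprintf("closed contour needs >= 3 points, got %d", n))
  structure(list(points = points, label = label,
                 plane_id = as.character(plane_id), closed = isTRUE(closed)),
            class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d %s on %s: %d points%s>\n", x$label, x$plane_id,
              nrow(x$points), if (x$closed) ", closed" else ", open"))
  invisible(x)
}

#' Project a planar contour into patient coordinates
#'
#' Maps pixel coordinates (u, v) on an imaging plane to 3D points in the
#' patient-based coordinate system:
#' \deqn{p = P + u \Delta u \, U + v \Delta v \, V}
#' where P is the plane position and U, V its row/column direction cosines.
#' Pixel indices are 0-based: (0, 0) maps onto P exactly.
#'
#' @param contour a [contour2d()], or a plain matrix of (u, v) coordinates.
#' @param meta the [plane_meta()] of the plane the contour lies on.
#' @return Numeric matrix of 3D points (mm), one row per contour point.
#' @export
project_contour_to_3d <- function(contour, meta) {
  if (!inherits(meta, "plane_meta"))
    stop_lheart("lheart_invalid_metadata", "meta must be a plane_meta object")
  uv <- if (inherits(contour, "contour2d")) contour$points
        else as_point_matrix(contour, 2, "contour points")
  out <- outer(uv[, 1] * meta$spacing[1], meta$row_dir) +
         outer(uv[, 2] * meta$spacing[2], meta$col_dir)
  out + rep(meta$position, each = nrow(out))
}

#' Assemble a contour study
#'
#' A study bundles the per-plane contours with their plane metadata; it is
#' the unit the reconstruction pipeline operates on.
#'
#' @param contours list of [contour2d()] objects.
#' @param planes list of [plane_meta()] objects (names are ignored; the
#'   `plane_id` fields are used).
#' @return A `contour_study` object.
#' @export
contour_study <- function(contours, planes) {
  if (!all(vapply(contours, inherits, TRUE, "contour2d")))
    stop_lheart("lheart_parameter_error", "contours must be contour2d objects")
  if (!all(vapply(planes, inherits, TRUE, "plane_meta")))
    stop_lheart("lheart_parameter_error", "planes must be plane_meta objects")
  ids <- vapply(planes, `[[`, "", "plane_id")
  if (anyDuplicated(ids))
    stop_lheart("lheart_parameter_error", "duplicate plane_id in planes")
  planes <- setNames(planes, ids)
  for (ct in contours)
    if (!ct$plane_id %in% ids)
      stop_lheart("lheart_referential_integrity", sprintf(
        "contour references unknown plane_id '%s'", ct$plane_id))
  structure(list(contours = contours, planes = planes), class = "contour_study")
}

#' @export
print.contour_study <- function(x, ...) {
  v <- vapply(x$planes, `[[`, "", "view")
  cat(sprintf("<contour_study: %d contours on %d planes (%d sax, %d lax)>\n",
              length(x$contours), length(x$planes), sum(v == "sax"),
              sum(v != "sax")))
  invisible(x)
}

STUDY_FORMAT <- "lheart-study"
STUDY_VERSION <- 1L

#' Read / write a contour study file
#'
#' The study file is a versioned JSON document with a `planes` array
#' (plane_id, view, position, row_dir, col_dir, spacing) and a `contours`
#' array (plane_id, label, closed, points). Coordinates are written in full
#' double precision, so write/read round-trips are exact.
#'
#' @param path file path.
#' @return `read_study` returns a `contour_study`.
#' @export
read_study <- function(path) {
  if (!file.exists(path))
    stop_lheart("lheart_parse_error", sprintf("study file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_lheart("lheart_parse_error",
                    sprintf("cannot parse study file %s: %s", path,
                            conditionMessage(e))))
  if (!identical(doc$format, STUDY_FORMAT))
    stop_lheart("lheart_parse_error",
                sprintf("not a %s file: %s", STUDY_FORMAT, path))
  planes <- lapply(doc$planes, function(p)
    plane_meta(position = unlist(p$position), row_dir = unlist(p$row_dir),
               col_dir = unlist(p$col_dir), spacing = unlist(p$spacing),
               plane_id = p$plane_id, view = p$view))
  contours <- lapply(seq_along(doc$contours), function(i) {
    ct <- doc$contours[[i]]
    pts <- do.call(rbind, lapply(ct$points, unlist))
    if (is.null(pts))
      stop_lheart("lheart_parse_error",
                  sprintf("contour record %d has no points", i))
    contour2d(pts, label = ct$label, plane_id = ct$plane_id,
              closed = isTRUE(ct$closed))
  })
  contour_study(contours, planes)
}

#' @rdname read_study
#' @param study a `contour_study`.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "contour_study"))
  doc <- list(
    format = STUDY_FORMAT, version = STUDY_VERSION,
    planes = lapply(unname(study$planes), function(p)
      list(plane_id = p$plane_id, view = p$view, position = p$position,
           row_dir = p$row_dir, col_dir = p$col_dir, spacing = p$spacing)),
    contours = lapply(study$contours, function(ct)
      list(plane_id = ct$plane_id, label = ct$label, closed = ct$closed,
           points = ct$points)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project all contours of a study into one 3D point cloud
#'
#' @param study a `contour_study`.
#' @return A `cloud3d` object: matrix `points` (n x 3, mm) with parallel
#'   per-point vectors `label`, `plane_id` and `view`.
#' @export
project_study <- function(study) {
  stopifnot(inherits(study, "contour_study"))
  parts <- lapply(study$contours, function(ct) {
    meta <- study$planes[[ct$plane_id]]
    project_contour_to_3d(ct, meta)
  })
  n <- vapply(parts, nrow, 0L)
  cloud3d(points = do.call(rbind, parts),
          label = rep(vapply(study$contours, `[[`, "", "label"), n),
          plane_id = rep(vapply(study$contours, `[[`, "", "plane_id"), n),
          view = rep(vapply(study$contours, function(ct)
            study$planes[[ct$plane_id]]$view, FUN.VALUE = ""), n))
}

#' Labelled 3D point cloud
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param label,plane_id,view per-point character vectors (recycled if
#'   length 1).
#' @export
cloud3d <- function(points, label = "LV", plane_id = "plane", view = "sax") {
  points <- as_point_matrix(points)
  n <- nrow(points)
  rec <- function(x) if (length(x) == 1) rep(x, n) else as.character(x)
  label <- rec(label); plane_id <- rec(plane_id); view <- rec(view)
  if (length(label) != n || length(plane_id) != n || length(view) != n)
    stop_lheart("lheart_parameter_error",
                "labels/plane ids/views must match the number of points")
  structure(list(points = points, label = label, plane_id = plane_id,
                 view = view), class = "cloud3d")
}

#' @export
print.cloud3d <- function(x, ...) {
  cat(sprintf("<cloud3d: %d points (%s)>\n", nrow(x$points),
              paste(sprintf("%s:%d", names(table(x$view)), table(x$view)),
                    collapse = ", ")))
  invisible(x)
}
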