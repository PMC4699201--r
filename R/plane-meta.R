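#' Imaging-plane metadata
#'
#' Describes the pose of one imaging plane in the patient-based (DICOM LPS)
#' coordinate system: the 3D position of the first pixel, the direction
#' cosines of the pixel row and column axes, and the pixel spacing. These are
#' the fields of the DICOM attributes ImagePositionPatient (0020,0032),
#' ImageOrientationPatient (0020,0037) and PixelSpacing (0028,0030).
#'
#' Direction cosines are validated to be unit length and mutually orthogonal
#' within `1e-6` after re-normalisation; vectors further off are rejected.
#'
#' @param position numeric length-3, plane origin in mm.
#' @param row_dir,col_dir numeric length-3 unit direction cosines of the
#'   pixel row (u) and column (v) axes.
#' @param spacing numeric length-2, mm per pixel along (u, v).
#' @param plane_id character scalar identifying the plane.
#' @param view one of `"sax"`, `"2ch"`, `"3ch"`, `"4ch"`.
#' @return A `plane_meta` object.
#' @export
plane_meta <- function(position, row_dir, col_dir, spacing,
                       plane_id = "plane", view = c("sax", "2ch", "3ch", "4ch")) {
  view <- match.arg(view)
  position <- as.numeric(position)
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  spacing <- as.numeric(spacing)
  if (length(position) != 3 || length(row_dir) != 3 || length(col_dir) != 3 ||
      length(spacing) != 2 || anyNA(c(position, row_dir, col_dir, spacing)))
    stop_lheart("lheart_invalid_metadata",
                "plane metadata must have 3-vector position/directions and 2-vector spacing")
  tol <- 1e-6
  nu <- vnorm(row_dir)
  nv <- vnorm(col_dir)
  if (abs(nu - 1) > tol || abs(nv - 1) > tol)
    stop_lheart("lheart_invalid_metadata", sprintf(
      "direction cosines are not unit length (|row|=%.8f, |col|=%.8f)", nu, nv))
  row_dir <- row_dir / nu
  col_dir <- col_dir / nv
  if (abs(sum(row_dir * col_dir)) > tol)
    stop_lheart("lheart_invalid_metadata", sprintf(
      "direction cosines are not orthogonal (dot = %.2e)", sum(row_dir * col_dir)))
  if (any(spacing <= 0))
    stop_lheart("lheart_invalid_metadata", "pixel spacing must be positive")
  # normalise IEEE negative zeros so serialisation round-trips bytewise
  position[position == 0] <- 0
  row_dir[row_dir == 0] <- 0
  col_dir[col_dir == 0] <- 0
  structure(
    list(position = position, row_dir = row_dir, col_dir = col_dir,
         spacing = spacing, plane_id = as.character(plane_id), view = view),
    class = "plane_meta")
}

#' @export
print.plane_meta <- function(x, ...) {
  cat(sprintf("<plane %s [%s] pos=(%.1f, %.1f, %.1f) spacing=(%g, %g) mm>\n",
              x$plane_id, x$view, x$position[1], x$position[2], x$position[3],
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

plane_normal <- function(meta) {
  n <- c(meta$row_dir[2] * meta$col_dir[3] - meta$row_dir[3] * meta$col_dir[2],
         meta$row_dir[3] * meta$col_dir[1] - meta$row_dir[1] * meta$col_dir[3],
         meta$row_dir[1] * meta$col_dir[2] - meta$row_dir[2] * meta$col_dir[1])
  n / vnorm(n)
}

#' Build plane metadata from DICOM header attributes
#'
#' Maps the raw values of ImagePositionPatient, ImageOrientationPatient and
#' PixelSpacing into a [plane_meta()]. The first orientation triple is the
#' row (u) direction, the second the column (v) direction. PixelSpacing is
#' stored in DICOM as (row spacing, column spacing); the in-plane u axis
#' advances along pixel columns, so `spacing = (PixelSpacing[2],
#' PixelSpacing[1])`, i.e. du is the DICOM column spacing.
#'
#' @param fields named list with elements `ImagePositionPatient` (3 numbers),
#'   `ImageOrientationPatient` (6 numbers) and `PixelSpacing` (2 numbers).
#' @inheritParams plane_meta
#' @return A `plane_meta` object.
#' @export
extract_plane_meta <- function(fields, plane_id = "plane", view = "sax") {
  need <- c(ImagePositionPatient = "(0020,0032)",
            ImageOrientationPatient = "(0020,0037)",
            PixelSpacing = "(0028,0030)")
  missing_at <- setdiff(names(need), names(fields))
  if (length(missing_at) > 0)
    stop_lheart("lheart_missing_metadata", paste0(
      "missing DICOM attribute(s): ",
      paste(sprintf("%s %s", missing_at, need[missing_at]), collapse = ", ")))
  pos <- as.numeric(fields$ImagePositionPatient)
  ori <- as.numeric(fields$ImageOrientationPatient)
  sp <- as.numeric(fields$PixelSpacing)
  if (length(ori) != 6)
    stop_lheart("lheart_invalid_metadata",
                "ImageOrientationPatient must contain 6 direction cosines")
  plane_meta(position = pos, row_dir = ori[1:3], col_dir = ori[4:6],
             spacing = c(sp[2], sp[1]), plane_id = plane_id, view = view)
}
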