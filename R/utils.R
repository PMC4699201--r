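# classed errors so callers/tests can dispatch on failure mode
stop_lheart <- function(class, msg, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "lheart_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

warn_lheart <- function(class, msg) {
  warning(structure(
    class = c(class, "lheart_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

as_point_matrix <- function(x, ncol = 3, what = "points") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol)
    stop_lheart("lheart_parameter_error",
                sprintf("%s must have %d columns, got %d", what, ncol, ncol(x)))
  if (anyNA(x))
    stop_lheart("lheart_parameter_error", sprintf("%s contain NA", what))
  dimnames(x) <- NULL
  x
}

vnorm <- function(v) sqrt(sum(v^2))

# nearest-neighbour distances from each row of x to the point set y
nn_dist <- function(x, y) {
  x <- as_point_matrix(x)
  y <- as_point_matrix(y)
  cpp_nn(x, y)$dist
}

pad3d <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 2) x <- cbind(x, 0)
  as_point_matrix(x)
}

#' Hausdorff distance between two point sets
#'
#' Computes \eqn{d_H(X, Y) = \max(\sup_x d(x, Y), \sup_y d(y, X))}, the
#' smallest dilation radius for which each set is contained in the dilated
#' other. Accepts 2-column (in-plane) or 3-column coordinate matrices;
#' 2D inputs are embedded at z = 0.
#'
#' @param x,y numeric matrices of points (rows), 2 or 3 columns, in mm.
#' @return Hausdorff distance in mm.
#' @export
hausdorff <- function(x, y) {
  if (is.null(x) || is.null(y) || NROW(x) == 0 || NROW(y) == 0)
    stop_lheart("lheart_undefined_distance",
                "Hausdorff distance is undefined for empty sets")
  x <- pad3d(x)
  y <- pad3d(y)
  max(max(cpp_nn(x, y)$dist), max(cpp_nn(y, x)$dist))
}
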