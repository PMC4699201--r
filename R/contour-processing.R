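#' Signed area of a planar polygon
#'
#' Shoelace formula. For 3D input the polygon is projected onto the plane
#' orthogonal to `normal`; the sign is positive when the polygon winds
#' counter-clockwise about `normal` (right-hand rule).
#'
#' @param points n x 2 or n x 3 polygon vertices (closed implicitly, first
#'   vertex not repeated).
#' @param normal reference normal for 3D input; default +z.
#' @return signed area in mm^2.
#' @export
signed_area <- function(points, normal = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop_lheart("lheart_degenerate_contour",
                "polygon needs at least 3 vertices")
  uv <- if (ncol(points) == 2) points else project_to_plane_basis(points, normal)
  n <- nrow(uv)
  j <- c(2:n, 1)
  sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2]) / 2
}

# orthonormal in-plane basis (b1, b2) with b1 x b2 = normal
plane_basis <- function(normal) {
  normal <- normal / vnorm(normal)
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- a - sum(a * normal) * normal
  b1 <- b1 / vnorm(b1)
  b2 <- c(normal[2] * b1[3] - normal[3] * b1[2],
          normal[3] * b1[1] - normal[1] * b1[3],
          normal[1] * b1[2] - normal[2] * b1[1])
  rbind(b1, b2)
}

project_to_plane_basis <- function(points, normal) {
  B <- plane_basis(normal)
  points %*% t(B)
}

#' Re-orient a closed contour counter-clockwise
#'
#' Reverses the vertex order when the signed area about `normal` is
#' negative, keeping the first vertex first. Idempotent.
#'
#' @inheritParams signed_area
#' @return the contour with positive signed area.
#' @export
reorient_ccw <- function(points, normal = c(0, 0, 1)) {
  a <- signed_area(points, normal)
  if (a == 0)
    stop_lheart("lheart_degenerate_contour", "polygon has zero area")
  if (a < 0) {
    n <- nrow(points)
    points <- points[c(1, n:2), , drop = FALSE]
  }
  points
}

# periodic PCHIP through closed-contour vertices, parameterised by
# cumulative chord length; the knot sequence is wrap-padded by 3 vertices
# on each side so the sampled central period is C1 across the seam
pchip_closed <- function(points, t_out_frac) {
  n <- nrow(points)
  d <- ncol(points)
  seg <- sqrt(rowSums((points[c(2:n, 1), , drop = FALSE] - points)^2))
  total <- sum(seg)
  t_knot <- c(0, cumsum(seg))[1:n]
  pad <- 3L
  pre <- (n - pad + 1):n
  post <- 1:pad
  tt <- c(t_knot[pre] - total, t_knot, t_knot[post] + total)
  pp <- rbind(points[pre, , drop = FALSE], points,
              points[post, , drop = FALSE])
  t_out <- t_out_frac * total
  out <- matrix(0, length(t_out), d)
  for (j in seq_len(d)) out[, j] <- pracma::pchip(tt, pp[, j], t_out)
  out
}

#' Resample a closed contour to N points
#'
#' Fits a shape-preserving piecewise cubic Hermite (PCHIP) curve through
#' the contour vertices, parameterised by cumulative chord length with
#' periodic closure, and samples it at `n` uniform parameter values
#' starting at the first vertex. The curve interpolates every original
#' vertex, so resampling at the original parameters reproduces the input.
#' Self-intersections of the fitted curve are not detected.
#'
#' @param points closed contour vertices (n0 x 2 or n0 x 3), at least 4.
#' @param n number of output points, at least 4.
#' @return n x d matrix on the interpolating curve; the first output point
#'   equals the first input vertex.
#' @export
resample_contour <- function(points, n) {
  points <- as.matrix(points)
  if (nrow(points) < 4)
    stop_lheart("lheart_parameter_error",
                "closed-contour resampling needs >= 4 vertices")
  if (!is.numeric(n) || n < 4)
    stop_lheart("lheart_parameter_error", "n must be >= 4")
  pchip_closed(points, seq(0, 1, length.out = n + 1)[1:n])
}

#' Match two contours by circular shift
#'
#' Finds the circular shift `k` of `other` that minimises the mean
#' point-wise Euclidean distance to `reference`; both contours must have
#' the same number of points and the same orientation. The search is
#' exhaustive over all N shifts; ties resolve to the smallest `k`.
#'
#' @param reference,other contour point matrices with equal row counts.
#' @return integer shift in `[0, N)`; applying
#'   `other[((seq_len(N) - 1 + k) %% N) + 1, ]` realises the minimum.
#' @export
match_contours <- function(reference, other) {
  reference <- as.matrix(reference)
  other <- as.matrix(other)
  n <- nrow(reference)
  if (nrow(other) != n)
    stop_lheart("lheart_parameter_error",
                "contours must have equal point counts")
  best_k <- 0L
  best <- Inf
  for (k in 0:(n - 1)) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    m <- mean(sqrt(rowSums((reference - other[idx, , drop = FALSE])^2)))
    if (m < best) {
      best <- m
      best_k <- k
    }
  }
  structure(best_k, mean_dist = best)
}

apply_shift <- function(points, k) {
  n <- nrow(points)
  points[((seq_len(n) - 1 + k) %% n) + 1, , drop = FALSE]
}

#' Re-formulate a stack of parallel contours as a contour matrix
#'
#' Sorts the contours of one group (LV, LA or AO) by their position along
#' the stack normal, re-orients each counter-clockwise, resamples each to
#' `n` points, and matches each contour to its lower neighbour by circular
#' shift so that every column of the resulting L x n grid is a
#' point-correspondence track running up the stack.
#'
#' @param contours list of contour point matrices (3D, one per slice).
#' @param levels numeric positions of the contours along the stack normal
#'   (mm); must be distinct.
#' @param n points per contour after resampling.
#' @param normal stack normal used for the orientation convention.
#' @param label group label carried through to the result.
#' @return A `contour_matrix`: list with `points` (L x n x 3 array),
#'   `levels` (sorted), `label`.
#' @export
build_matrix <- function(contours, levels, n = 48, normal = c(0, 0, 1),
                         label = "LV") {
  if (length(contours) < 2)
    stop_lheart("lheart_parameter_error",
                "a contour stack needs at least 2 contours")
  if (length(levels) != length(contours))
    stop_lheart("lheart_parameter_error", "levels must match contours")
  if (min(diff(sort(levels))) < 1e-9)
    stop_lheart("lheart_ambiguous_stack",
                "duplicate slice levels in contour stack")
  ord <- order(levels)
  contours <- contours[ord]
  levels <- levels[ord]
  L <- length(contours)
  pts <- array(0, c(L, n, 3))
  for (i in seq_len(L)) {
    ct <- reorient_ccw(as.matrix(contours[[i]]), normal)
    pts[i, , ] <- resample_contour(ct, n)
  }
  for (i in seq_len(L - 1)) {
    k <- match_contours(pts[i, , ], pts[i + 1, , ])
    pts[i + 1, , ] <- apply_shift(pts[i + 1, , ], as.integer(k))
  }
  structure(list(points = pts, levels = levels, label = label,
                 normal = normal / vnorm(normal)),
            class = "contour_matrix")
}

#' @export
print.contour_matrix <- function(x, ...) {
  cat(sprintf("<contour_matrix %s: %d levels x %d points, span %.1f mm>\n",
              x$label, dim(x$points)[1], dim(x$points)[2],
              diff(range(x$levels))))
  invisible(x)
}

#' Interpolate a contour matrix to M levels
#'
#' Inter-contour interpolation: each column track of the L x N matrix is
#' interpolated coordinate-wise by PCHIP against the physical slice
#' position, and evaluated at `m` uniformly spaced levels spanning the
#' original level range (no extrapolation). Output levels that coincide
#' with input levels reproduce the input points.
#'
#' @param cm a `contour_matrix`.
#' @param m number of output levels, at least the input level count.
#' @return A denser `contour_matrix` (m x N).
#' @export
interpolate_levels <- function(cm, m) {
  stopifnot(inherits(cm, "contour_matrix"))
  L <- dim(cm$points)[1]
  n <- dim(cm$points)[2]
  if (!is.numeric(m) || m < L)
    stop_lheart("lheart_parameter_error",
                sprintf("m (%s) must be >= number of input levels (%d)",
                        format(m), L))
  new_levels <- seq(cm$levels[1], cm$levels[L], length.out = m)
  out <- array(0, c(m, n, 3))
  for (j in seq_len(n)) {
    for (d in 1:3) {
      y <- cm$points[, j, d]
      out[, j, d] <- if (L == 2) {
        # PCHIP through 2 knots is the linear interpolant
        y[1] + (y[2] - y[1]) * (new_levels - cm$levels[1]) /
          (cm$levels[2] - cm$levels[1])
      } else {
        pracma::pchip(cm$levels, y, new_levels)
      }
    }
  }
  structure(list(points = out, levels = new_levels, label = cm$label,
                 normal = cm$normal),
            class = "contour_matrix")
}

matrix_points <- function(cm) {
  d <- dim(cm$points)
  matrix(cm$points, d[1] * d[2], 3)
}

# per-level centroids: guaranteed-inside blood-pool anchor points
matrix_row_centroids <- function(cm) {
  t(apply(cm$points, 1, colMeans))
}

#' Densify the short-axis contour groups
#'
#' Runs the full intra/inter-contour interpolation pipeline
#' ([build_matrix()] then [interpolate_levels()]) on each single-structure
#' short-axis group (LV, LA, AO) of a projected study cloud. Contours with
#' the `MERGED` label (the ventricular in/outflow bifurcation, where
#' point correspondence across slices is undefined) are excluded from
#' interpolation and passed through unchanged. Groups with fewer than two
#' contours also pass through, with a warning.
#'
#' @param sax_contours list of lists, one per short-axis contour, each with
#'   elements `points` (k x 3 matrix, mm) and `label`.
#' @param n points per resampled contour.
#' @param m integer, number of output levels per group, or `NULL` to choose
#'   it so that the inter-level spacing approximates the intra-contour
#'   point spacing.
#' @param normal short-axis stack normal (apex-to-base).
#' @return list with `matrices` (named list of `contour_matrix` per
#'   densified group), `passthrough` (matrix of MERGED and un-interpolated
#'   points), and `points` (all densified + passthrough points combined).
#' @export
densify_groups <- function(sax_contours, n = 48, m = NULL,
                           normal = c(0, 0, 1)) {
  labels <- vapply(sax_contours, `[[`, "", "label")
  normal <- normal / vnorm(normal)
  matrices <- list()
  pass <- list()
  for (g in c("LV", "LA", "AO")) {
    sel <- which(labels == g)
    if (length(sel) < 2) {
      if (length(sel) > 0) {
        warn_lheart("lheart_sparse_group", sprintf(
          "group %s has %d contour(s); passed through uninterpolated",
          g, length(sel)))
        pass <- c(pass, lapply(sax_contours[sel], `[[`, "points"))
      }
      next
    }
    pts <- lapply(sax_contours[sel], `[[`, "points")
    levels <- vapply(pts, function(p) mean(p %*% normal), 0)
    cm <- build_matrix(pts, levels, n = n, normal = normal, label = g)
    m_g <- if (is.null(m)) {
      # inter-level spacing ~ intra-contour point spacing
      per <- mean(apply(cm$points, 1, function(p) {
        p <- matrix(p, ncol = 3)
        sum(sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2)))
      }))
      span <- diff(range(cm$levels))
      max(dim(cm$points)[1], round(span / (per / n)) + 1)
    } else m
    matrices[[g]] <- interpolate_levels(cm, m_g)
  }
  merged <- lapply(sax_contours[labels == "MERGED"], `[[`, "points")
  pass <- c(pass, merged)
  passthrough <- if (length(pass)) do.call(rbind, pass) else
    matrix(0, 0, 3)
  dense <- if (length(matrices)) do.call(rbind, lapply(matrices,
                                                       matrix_points)) else
    matrix(0, 0, 3)
  list(matrices = matrices, passthrough = passthrough,
       merged = merged, points = rbind(dense, passthrough))
}
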