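#' Rigid transform
#'
#' A proper rigid-body motion `p -> R p + v` used to correct per-plane
#' breath-hold misalignment. The rotation must be proper orthonormal
#' (R'R = I, det R = +1) within `1e-9`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop_lheart("lheart_parameter_error",
                "rigid transform needs a 3x3 rotation and a 3-vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_lheart("lheart_parameter_error",
                "rotation must be proper orthonormal (det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation %.3f mm>\n",
              ang, vnorm(x$translation)))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Apply or invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix.
#' @return `apply_rigid`: transformed n x 3 matrix. `invert_rigid`: the
#'   inverse transform.
#' @export
apply_rigid <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_point_matrix(points)
  points %*% t(transform$rotation) +
    rep(transform$translation, each = nrow(points))
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' @rdname apply_rigid
#' @param a,b transforms; the composition applies `b` first, then `a`.
#' @export
compose_rigid <- function(a, b) {
  R <- a$rotation %*% b$rotation
  # re-orthonormalise to keep drift below 1e-9 under repeated composition
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Mutual subset filtering of two point clouds
#'
#' Iteratively removes from each cloud the points farther than `epsilon`
#' from the current subset of the other cloud, until no point is removed.
#' The surviving subsets form the overlap region on which rigid
#' registration is well posed, and satisfy: (1) their Hausdorff distance is
#' at most `epsilon`; (2) if `epsilon` exceeds the Hausdorff distance of
#' the input clouds nothing is removed; (3) the subsets grow monotonically
#' with `epsilon`.
#'
#' @param c_x,c_y point matrices (n x 3, mm).
#' @param epsilon neighbourhood radius in mm.
#' @return list with `x_sub`, `y_sub` (the filtered subsets), logical
#'   keep-masks `x_keep`, `y_keep`, and the number of sweeps `iterations`.
#' @export
mutual_subset <- function(c_x, c_y, epsilon) {
  c_x <- as_point_matrix(c_x)
  c_y <- as_point_matrix(c_y)
  if (nrow(c_x) == 0 || nrow(c_y) == 0)
    stop_lheart("lheart_parameter_error", "point clouds must be non-empty")
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_lheart("lheart_parameter_error", "epsilon must be positive")
  kx <- rep(TRUE, nrow(c_x))
  ky <- rep(TRUE, nrow(c_y))
  it <- 0L
  repeat {
    it <- it + 1L
    last <- c(sum(kx), sum(ky))
    ox <- nn_dist(c_x[kx, , drop = FALSE], c_y[ky, , drop = FALSE]) > epsilon
    kx[kx] <- !ox
    if (!any(kx))
      stop_lheart("lheart_epsilon_too_small", sprintf(
        "mutual subset of first cloud became empty (epsilon = %g; last sizes %d/%d)",
        epsilon, last[1], last[2]), sizes = last)
    oy <- nn_dist(c_y[ky, , drop = FALSE], c_x[kx, , drop = FALSE]) > epsilon
    ky[ky] <- !oy
    if (!any(ky))
      stop_lheart("lheart_epsilon_too_small", sprintf(
        "mutual subset of second cloud became empty (epsilon = %g; last sizes %d/%d)",
        epsilon, last[1], last[2]), sizes = last)
    if (!any(ox) && !any(oy)) break
  }
  list(x_sub = c_x[kx, , drop = FALSE], y_sub = c_y[ky, , drop = FALSE],
       x_keep = kx, y_keep = ky, iterations = it)
}

# one closed-form orthogonal-Procrustes (Kabsch) step for paired points,
# with the standard reflection guard
kabsch <- function(moving, target) {
  mm <- colMeans(moving)
  mt <- colMeans(target)
  H <- crossprod(sweep(moving, 2, mm), sweep(target, 2, mt))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, mt - as.vector(R %*% mm))
}

#' Iterative closest point rigid registration
#'
#' Classic point-to-point ICP: alternate nearest-neighbour correspondence
#' against the fixed reference with a closed-form orthogonal-Procrustes
#' update, starting from the identity. Iterations stop when the RMS
#' nearest-neighbour distance changes by less than `tol` or after
#' `max_iter` iterations. The RMS history is non-increasing.
#'
#' @param reference fixed point set (n x 3, mm).
#' @param moving point set to align (m x 3, mm); at least 3 non-collinear
#'   points.
#' @param max_iter,tol convergence controls (`tol` in mm of RMS change).
#' @return A [rigid_transform()] with attributes `rms` (final RMS, mm),
#'   `history` (RMS per iteration) and `iterations`.
#' @export
icp_rigid <- function(reference, moving, max_iter = 100, tol = 1e-6) {
  reference <- as_point_matrix(reference)
  moving <- as_point_matrix(moving)
  if (nrow(moving) < 3 || nrow(reference) < 1)
    stop_lheart("lheart_degenerate_geometry",
                "ICP needs >= 3 moving points and a non-empty reference")
  sv <- svd(sweep(moving, 2, colMeans(moving)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop_lheart("lheart_degenerate_geometry",
                "moving point set is collinear or coincident")
  cur <- rigid_transform()
  pts <- moving
  history <- numeric(0)
  prev <- Inf
  for (i in seq_len(max_iter)) {
    nn <- cpp_nn(pts, reference)
    rms <- sqrt(mean(nn$dist^2))
    history <- c(history, rms)
    if (abs(prev - rms) < tol) break
    prev <- rms
    step <- kabsch(pts, reference[nn$idx, , drop = FALSE])
    cur <- compose_rigid(step, cur)
    pts <- apply_rigid(cur, moving)
  }
  structure(cur, rms = history[length(history)], history = history,
            iterations = length(history))
}

#' Register one long-axis cloud to the short-axis cloud
#'
#' Computes the neighbourhood radius `epsilon = alpha * d_H(C_sax, C_lax)`,
#' filters both clouds by [mutual_subset()], then runs [icp_rigid()] with
#' the short-axis subset fixed as reference.
#'
#' @param c_sax short-axis reference cloud (n x 3).
#' @param c_lax long-axis cloud to align (m x 3).
#' @param alpha fraction of the Hausdorff distance used as `epsilon`;
#'   sensible values lie in 0.2 - 0.5.
#' @param max_iter,tol passed to [icp_rigid()].
#' @return list with `transform` (a [rigid_transform()]) and `diagnostics`
#'   (epsilon, subset sizes, ICP iterations, RMS, Hausdorff distance of the
#'   subsets before and after registration).
#' @export
register_pair <- function(c_sax, c_lax, alpha = 0.35, max_iter = 100,
                          tol = 1e-6) {
  if (!is.numeric(alpha) || alpha < 0.2 || alpha > 0.5)
    stop_lheart("lheart_parameter_error",
                sprintf("alpha must lie in [0.2, 0.5], got %g", alpha))
  c_sax <- as_point_matrix(c_sax)
  c_lax <- as_point_matrix(c_lax)
  dh0 <- hausdorff(c_sax, c_lax)
  eps <- alpha * dh0
  sub <- mutual_subset(c_sax, c_lax, eps)
  tr <- icp_rigid(sub$x_sub, sub$y_sub, max_iter = max_iter, tol = tol)
  dh_pre <- hausdorff(sub$x_sub, sub$y_sub)
  dh_post <- hausdorff(sub$x_sub, apply_rigid(tr, sub$y_sub))
  list(transform = tr,
       diagnostics = list(
         epsilon = eps, alpha = alpha, hausdorff_full = dh0,
         sax_subset = nrow(sub$x_sub), lax_subset = nrow(sub$y_sub),
         subset_iterations = sub$iterations,
         icp_iterations = attr(tr, "iterations"),
         rms = attr(tr, "rms"),
         hausdorff_subsets_pre = dh_pre,
         hausdorff_subsets_post = dh_post))
}

#' Register all long-axis clouds of a study
#'
#' Performs three independent pairwise registrations, \{sax, 2ch\},
#' \{sax, 3ch\} and \{sax, 4ch\}, with the short-axis cloud always fixed.
#' The short-axis subset selected by the mutual filtering may differ
#' between pairs. Registration moves points but never drops them.
#'
#' @param cloud a [cloud3d()] containing `sax` points and at least one of
#'   the long-axis views.
#' @inheritParams register_pair
#' @return list with `cloud` (the input cloud with long-axis points
#'   replaced by their registered positions), `transforms` (named by view)
#'   and `diagnostics` (named by view).
#' @export
register_study <- function(cloud, alpha = 0.35, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(cloud, "cloud3d"))
  sax <- cloud$points[cloud$view == "sax", , drop = FALSE]
  if (nrow(sax) == 0)
    stop_lheart("lheart_parameter_error", "study has no short-axis points")
  views <- intersect(c("2ch", "3ch", "4ch"), unique(cloud$view))
  transforms <- list()
  diagnostics <- list()
  out <- cloud
  for (v in views) {
    sel <- cloud$view == v
    res <- tryCatch(
      register_pair(sax, cloud$points[sel, , drop = FALSE], alpha = alpha,
                    max_iter = max_iter, tol = tol),
      error = function(e) stop_lheart(class(e)[1], sprintf(
        "registration of pair {sax, %s} failed: %s", v, conditionMessage(e))))
    transforms[[v]] <- res$transform
    diagnostics[[v]] <- res$diagnostics
    out$points[sel, ] <- apply_rigid(res$transform,
                                     cloud$points[sel, , drop = FALSE])
  }
  list(cloud = out, transforms = transforms, diagnostics = diagnostics)
}
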