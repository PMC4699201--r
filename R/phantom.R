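#' Analytic left-heart phantom specification
#'
#' The phantom is the union of three overlapping implicit shapes emulating
#' the left cardiac blood pool: an LV ellipsoid (long axis along +z, apex
#' at the bottom), a smaller LA ellipsoid sitting above and behind the LV
#' base, and an aortic tube of circular cross-section along a circular-arc
#' centerline rising from the LV outflow region. The three components are
#' blended with a smooth minimum so that slices through the junction
#' genuinely merge into a single contour, exercising the same three
#' short-axis cases seen in clinical delineations: LV only, separate
#' LA + AO, and a merged bifurcation contour.
#'
#' @param lv_semiaxes,la_semiaxes ellipsoid semi-axes, mm.
#' @param lv_center,la_center component centres, mm.
#' @param ao_radius aortic tube radius, mm.
#' @param ao_arc_center,ao_arc_radius,ao_arc_deg circular-arc centerline of
#'   the aorta in the y = 0 plane: 2D centre (x, z), radius, and angular
#'   range in degrees.
#' @param base_plane_offset z of the ventricular base region, mm
#'   (informational; the default component placement is expressed through
#'   the centres above).
#' @param blend_radius smooth-minimum blending scale, mm.
#' @param seed integer seed carried into downstream sampling.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(lv_semiaxes = c(26, 23, 45),
                         lv_center = c(0, 0, 0),
                         la_semiaxes = c(17, 15, 22),
                         la_center = c(-16, 0, 58),
                         ao_radius = 10,
                         ao_arc_center = c(40, 34),
                         ao_arc_radius = 30,
                         ao_arc_deg = c(100, 180),
                         base_plane_offset = 38,
                         blend_radius = 5,
                         seed = 1L) {
  spec <- structure(list(
    lv_semiaxes = as.numeric(lv_semiaxes), lv_center = as.numeric(lv_center),
    la_semiaxes = as.numeric(la_semiaxes), la_center = as.numeric(la_center),
    ao_radius = as.numeric(ao_radius),
    ao_arc_center = as.numeric(ao_arc_center),
    ao_arc_radius = as.numeric(ao_arc_radius),
    ao_arc_deg = as.numeric(ao_arc_deg),
    base_plane_offset = as.numeric(base_plane_offset),
    blend_radius = as.numeric(blend_radius),
    seed = as.integer(seed)), class = "phantom_spec")
  if (any(c(spec$lv_semiaxes, spec$la_semiaxes, spec$ao_radius,
            spec$ao_arc_radius, spec$blend_radius) <= 0))
    stop_lheart("lheart_invalid_spec", "all phantom lengths must be positive")
  comp <- component_functions(spec)
  # the components must overlap pairwise at the junctions
  seg_check <- function(f1, f2, p1, p2) {
    t_ <- seq(0, 1, length.out = 200)
    pts <- outer(1 - t_, p1) + outer(t_, p2)
    any(f1(pts) < 0 & f2(pts) < 0)
  }
  ao_start <- ao_point(spec, max(spec$ao_arc_deg))
  if (!seg_check(comp$lv, comp$la, spec$lv_center, spec$la_center) ||
      !seg_check(comp$lv, comp$ao, spec$lv_center, ao_start))
    stop_lheart("lheart_invalid_spec",
                "phantom components do not overlap at the junctions")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec: LV (%g, %g, %g) mm, LA (%g, %g, %g) mm, ",
                     "AO r=%g mm, blend %g mm, seed %d>\n"),
              x$lv_semiaxes[1], x$lv_semiaxes[2], x$lv_semiaxes[3],
              x$la_semiaxes[1], x$la_semiaxes[2], x$la_semiaxes[3],
              x$ao_radius, x$blend_radius, x$seed))
  invisible(x)
}

ao_point <- function(spec, deg) {
  th <- deg * pi / 180
  c(spec$ao_arc_center[1] + spec$ao_arc_radius * cos(th), 0,
    spec$ao_arc_center[2] + spec$ao_arc_radius * sin(th))
}

component_functions <- function(spec) {
  ell <- function(center, semi) {
    force(center); force(semi)
    function(p) {
      p <- pad3d(p)
      r <- sqrt(((p[, 1] - center[1]) / semi[1])^2 +
                ((p[, 2] - center[2]) / semi[2])^2 +
                ((p[, 3] - center[3]) / semi[3])^2)
      (r - 1) * min(semi)
    }
  }
  ao <- function(p) {
    p <- pad3d(p)
    cx <- spec$ao_arc_center[1]
    cz <- spec$ao_arc_center[2]
    dx <- p[, 1] - cx
    dz <- p[, 3] - cz
    r2d <- sqrt(dx^2 + dz^2)
    phi <- atan2(dz, dx) * 180 / pi
    phi[phi < 0] <- phi[phi < 0] + 360
    lo <- min(spec$ao_arc_deg); hi <- max(spec$ao_arc_deg)
    on_arc <- phi >= lo & phi <= hi
    d2d <- abs(r2d - spec$ao_arc_radius)
    # off the angular range the nearest centerline point is an arc endpoint
    d_end <- rep(Inf, nrow(p))
    for (deg in c(lo, hi)) {
      ep <- ao_point(spec, deg)
      d_end <- pmin(d_end, sqrt((p[, 1] - ep[1])^2 + (p[, 3] - ep[3])^2))
    }
    d2d[!on_arc] <- d_end[!on_arc]
    sqrt(d2d^2 + p[, 2]^2) - spec$ao_radius
  }
  list(lv = ell(spec$lv_center, spec$lv_semiaxes),
       la = ell(spec$la_center, spec$la_semiaxes),
       ao = ao)
}

#' Implicit scalar field of the phantom
#'
#' Returns `f(x)` with `f < 0` inside the blended left-heart shape and
#' `f > 0` outside. The blend is a log-sum-exp smooth minimum of the three
#' component fields with scale `blend_radius`.
#'
#' @param spec a [phantom_spec()].
#' @return function mapping an n x 3 matrix to n field values; the
#'   per-component fields are attached as attribute `components`.
#' @export
implicit_shape <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- component_functions(spec)
  k <- spec$blend_radius
  f <- function(p) {
    v <- cbind(comp$lv(p), comp$la(p), comp$ao(p))
    m <- apply(v, 1, min)
    # numerically stable smooth minimum
    m - k * log(rowSums(exp(-(v - m) / k)))
  }
  attr(f, "components") <- comp
  f
}

phantom_bbox <- function(spec, margin = NULL) {
  if (is.null(margin)) margin <- 3 * spec$blend_radius
  pts <- rbind(spec$lv_center - spec$lv_semiaxes,
               spec$lv_center + spec$lv_semiaxes,
               spec$la_center - spec$la_semiaxes,
               spec$la_center + spec$la_semiaxes)
  th <- seq(min(spec$ao_arc_deg), max(spec$ao_arc_deg), length.out = 41)
  arc <- cbind(spec$ao_arc_center[1] + spec$ao_arc_radius * cos(th * pi / 180),
               0,
               spec$ao_arc_center[2] + spec$ao_arc_radius * sin(th * pi / 180))
  pts <- rbind(pts, arc + spec$ao_radius, arc - spec$ao_radius)
  list(lo = apply(pts, 2, min) - margin, hi = apply(pts, 2, max) + margin)
}

#' Ground-truth surface of the phantom
#'
#' Marching-tetrahedra extraction of the zero level set on a regular grid.
#' The returned surface is watertight and genus 0 for the default
#' phantom.
#'
#' @param spec a [phantom_spec()].
#' @param resolution grid spacing, mm.
#' @return A [tri_surface()].
#' @export
ground_truth_mesh <- function(spec, resolution = 1) {
  f <- implicit_shape(spec)
  bb <- phantom_bbox(spec)
  for (attempt in 1:2) {
    axes <- lapply(1:3, function(j) seq(bb$lo[j], bb$hi[j], by = resolution))
    g <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
    vals <- f(g)
    m <- cpp_marching_tets(vals, length(axes[[1]]), length(axes[[2]]),
                           length(axes[[3]]),
                           c(bb$lo[1], bb$lo[2], bb$lo[3]),
                           rep(resolution, 3))
    surf <- tri_surface(m$vertices, m$faces)
    if (is_watertight(surf)) return(surf)
    bb$lo <- bb$lo - 5 * resolution  # clipped at the domain edge: expand
    bb$hi <- bb$hi + 5 * resolution
  }
  stop_lheart("lheart_degenerate_input",
              "could not extract a closed phantom surface")
}

default_geometry <- function() {
  list(sax_spacing = 8,          # inter-slice spacing, mm, no gap
       pixel_spacing = 1.43,     # in-plane resolution, mm/pixel
       sax_z = seq(-48, 88, by = 8),
       sax_u0 = c(-62, -45),     # plane origin (u, v) in mm
       sax_extent = c(125, 90),  # in-plane extent, mm
       lax_angles_deg = c(`3ch` = 0, `2ch` = 60, `4ch` = 120),
       lax_u0 = c(-70, -60),
       lax_extent = c(140, 155),
       points_spacing_mm = 4)    # emulated manual delineation density
}

point_in_poly <- function(pts, poly) {
  # even-odd rule, vectorised over pts
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

slice_plane <- function(f, comp, meta, npx, spacing_mm) {
  u_idx <- seq_len(npx[1]) - 1
  v_idx <- seq_len(npx[2]) - 1
  uv <- as.matrix(expand.grid(u = u_idx, v = v_idx))
  p3 <- project_contour_to_3d(uv, meta)
  vals <- matrix(f(p3), length(u_idx), length(v_idx))
  cl <- contourLines(x = u_idx, y = v_idx, z = vals, levels = 0)
  if (length(cl) == 0) return(list())
  out <- list()
  for (ct in cl) {
    pts <- cbind(ct$x, ct$y)
    n <- nrow(pts)
    if (n > 1 && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
    if (nrow(pts) < 8) next
    # contours clipped at the field of view are not usable sections
    if (min(pts) <= min(u_idx) + 1e-9 || max(pts[, 1]) >= max(u_idx) - 1e-9 ||
        max(pts[, 2]) >= max(v_idx) - 1e-9)
      next
    per_mm <- sum(sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2))) *
      meta$spacing[1]
    if (per_mm < 25) next  # sliver sections are not delineated
    # which anatomical components lie inside this contour?
    cand <- uv[point_in_poly(uv, pts), , drop = FALSE]
    if (nrow(cand) == 0) next
    c3 <- project_contour_to_3d(cand, meta)
    present <- c(LV = any(comp$lv(c3) < 0), LA = any(comp$la(c3) < 0),
                 AO = any(comp$ao(c3) < 0))
    label <- if (sum(present) >= 2) "MERGED" else
      if (!any(present)) next else names(present)[present]
    # emulate manual delineation density
    n_out <- max(12, round(per_mm / spacing_mm))
    pts <- resample_contour(pts, n_out)
    out[[length(out) + 1]] <- contour2d(pts, label = label,
                                        plane_id = meta$plane_id)
  }
  out
}

#' Slice the phantom into a contour study
#'
#' Emulates the clinical acquisition: a parallel short-axis stack at 8 mm
#' inter-slice spacing with no gap, plus three long-axis planes (two-,
#' three- and four-chamber-like) orthogonal to the short-axis stack and
#' rotated about the long axis, all at 1.43 mm pixel spacing. Each plane's
#' zero-level contours of the implicit shape are extracted, resampled to a
#' manual-delineation point density, and labelled LV, LA, AO, or MERGED
#' when the section passes through the blended bifurcation region. Planes
#' that miss the shape are omitted.
#'
#' @param spec a [phantom_spec()].
#' @param geometry acquisition geometry; see `lheart:::default_geometry()`.
#' @return A `contour_study`.
#' @export
slice_study <- function(spec, geometry = default_geometry()) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- implicit_shape(spec)
  comp <- attr(f, "components")
  g <- geometry
  planes <- list()
  contours <- list()
  px <- g$pixel_spacing
  for (i in seq_along(g$sax_z)) {
    meta <- plane_meta(
      position = c(g$sax_u0[1], g$sax_u0[2], g$sax_z[i]),
      row_dir = c(1, 0, 0), col_dir = c(0, 1, 0), spacing = c(px, px),
      plane_id = sprintf("sax_%02d", i), view = "sax")
    cts <- slice_plane(f, comp, meta, ceiling(g$sax_extent / px),
                       g$points_spacing_mm)
    if (length(cts) > 0) {
      planes[[meta$plane_id]] <- meta
      contours <- c(contours, cts)
    }
  }
  for (v in names(g$lax_angles_deg)) {
    th <- g$lax_angles_deg[[v]] * pi / 180
    e <- c(cos(th), sin(th), 0)
    meta <- plane_meta(
      position = c(g$lax_u0[1] * e[1], g$lax_u0[1] * e[2], g$lax_u0[2]),
      row_dir = e, col_dir = c(0, 0, 1), spacing = c(px, px),
      plane_id = paste0("lax_", v), view = v)
    cts <- slice_plane(f, comp, meta, ceiling(g$lax_extent / px),
                       g$points_spacing_mm)
    if (length(cts) > 0) {
      planes[[meta$plane_id]] <- meta
      contours <- c(contours, cts)
    }
  }
  contour_study(contours, planes)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / vnorm(v)
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / vnorm(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Rigidly perturb the long-axis planes of a study
#'
#' Emulates breath-hold misalignment: each long-axis plane receives an
#' independent rigid motion with rotation angle uniform in
#' `[0, max_rot_deg]` about a random axis through the plane's contour
#' centroid and translation of magnitude uniform in `[0, max_shift_mm]`.
#' The short-axis stack is never moved (it is the registration
#' reference). Deterministic for a fixed seed.
#'
#' @param study a `contour_study`.
#' @param max_shift_mm,max_rot_deg perturbation bounds.
#' @param seed integer seed.
#' @return list with `study` (perturbed) and `truth` (named list of
#'   [rigid_transform()] per long-axis plane mapping original 3D contour
#'   positions to their perturbed positions).
#' @export
perturb_study <- function(study, max_shift_mm = 5, max_rot_deg = 5,
                          seed = 1L) {
  stopifnot(inherits(study, "contour_study"))
  if (max_shift_mm < 0 || max_rot_deg < 0)
    stop_lheart("lheart_parameter_error", "perturbation bounds must be >= 0")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  out <- study
  truth <- list()
  for (pid in names(study$planes)) {
    meta <- study$planes[[pid]]
    if (meta$view == "sax") next
    cts <- Filter(function(ct) ct$plane_id == pid, study$contours)
    if (length(cts) == 0) next
    cen <- colMeans(do.call(rbind, lapply(cts, project_contour_to_3d,
                                          meta = meta)))
    ang <- runif(1, 0, max_rot_deg) * pi / 180
    R <- rotation_about_axis(random_unit_vector(), ang)
    t_ <- runif(1, 0, max_shift_mm) * random_unit_vector()
    v_ <- as.vector(t_ + cen - R %*% cen)
    tr <- rigid_transform(R, v_)
    truth[[pid]] <- tr
    out$planes[[pid]] <- plane_meta(
      position = apply_rigid(tr, matrix(meta$position, 1))[1, ],
      row_dir = as.vector(R %*% meta$row_dir),
      col_dir = as.vector(R %*% meta$col_dir),
      spacing = meta$spacing, plane_id = meta$plane_id, view = meta$view)
  }
  list(study = out, truth = truth)
}
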