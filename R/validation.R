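#' Intersect a surface with an imaging plane
#'
#' Cuts the triangulated surface with the plane of `meta` and chains the
#' triangle crossings into closed polygons, expressed in the plane's
#' physical in-plane coordinates (mm along `row_dir` and `col_dir`,
#' relative to the plane position). A watertight surface always yields
#' closed polygons; an open chain (non-watertight input) is an error.
#'
#' @param surface a [tri_surface()].
#' @param meta a [plane_meta()].
#' @return list of closed polygons (k x 2 matrices, mm); empty list if the
#'   plane misses the surface.
#' @export
intersect_mesh_plane <- function(surface, meta) {
  stopifnot(inherits(surface, "tri_surface"), inherits(meta, "plane_meta"))
  v <- surface$vertices
  f <- surface$triangles
  nrm <- plane_normal(meta)
  d <- as.vector(v %*% nrm) - sum(nrm * meta$position)
  # nudge exactly-on-plane vertices off the plane for a clean crossing test
  scale <- max(abs(d), 1)
  d[d == 0] <- 1e-12 * scale
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crosses <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crosses)) return(list())
  fc <- f[crosses, , drop = FALSE]

  # for each crossing triangle, the two cut edges give one segment;
  # endpoints are keyed by the mesh edge so chains connect exactly
  seg_from <- character(0); seg_to <- character(0)
  pt_of <- new.env(hash = TRUE)
  edge_cut <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (!exists(k, envir = pt_of, inherits = FALSE)) {
      t_ <- d[a] / (d[a] - d[b])
      assign(k, v[a, ] + t_ * (v[b, ] - v[a, ]), envir = pt_of)
    }
    k
  }
  for (i in seq_len(nrow(fc))) {
    tr <- fc[i, ]
    dd <- d[tr]
    neg <- tr[dd < 0]; pos <- tr[dd > 0]
    if (length(neg) == 1) {
      k1 <- edge_cut(neg, pos[1]); k2 <- edge_cut(neg, pos[2])
    } else {
      k1 <- edge_cut(neg[1], pos); k2 <- edge_cut(neg[2], pos)
    }
    seg_from <- c(seg_from, k1); seg_to <- c(seg_to, k2)
  }

  # chain segments into loops (each cut point touches exactly 2 segments
  # on a watertight surface)
  links <- split(c(seq_along(seg_from), seq_along(seg_to)),
                 c(seg_from, seg_to))
  used <- rep(FALSE, length(seg_from))
  loops <- list()
  for (start in seq_along(seg_from)) {
    if (used[start]) next
    used[start] <- TRUE
    loop_keys <- c(seg_from[start], seg_to[start])
    repeat {
      cur <- loop_keys[length(loop_keys)]
      nxt_seg <- setdiff(links[[cur]], which(used))
      if (length(nxt_seg) == 0) break
      s <- nxt_seg[1]
      used[s] <- TRUE
      nxt_key <- if (seg_from[s] == cur) seg_to[s] else seg_from[s]
      loop_keys <- c(loop_keys, nxt_key)
    }
    if (loop_keys[1] != loop_keys[length(loop_keys)])
      stop_lheart("lheart_open_intersection",
                  "open intersection chain; surface is not watertight")
    loop_keys <- loop_keys[-length(loop_keys)]
    if (length(loop_keys) >= 3) loops <- c(loops, list(loop_keys))
  }

  b <- rbind(meta$row_dir, meta$col_dir)
  lapply(loops, function(keys) {
    p3 <- do.call(rbind, lapply(keys, get, envir = pt_of))
    sweep(p3, 2, meta$position) %*% t(b)
  })
}

# ear-clipping triangulation of a simple polygon (n x 2) -> (n-2) x 3
earcut <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop_lheart("lheart_invalid_region", "polygon with < 3 vertices")
  if (n == 3) return(matrix(1:3, 1))
  a2 <- signed_area(poly)
  idx <- if (a2 < 0) rev(seq_len(n)) else seq_len(n)
  tris <- matrix(0L, 0, 3)
  cross2 <- function(o, a, b)
    (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  guard <- 0
  while (length(idx) > 3 && guard < 4 * n * n) {
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      guard <- guard + 1
      ip <- idx[if (i == 1) m else i - 1]
      ic <- idx[i]
      inx <- idx[if (i == m) 1 else i + 1]
      o <- poly[ip, ]; a <- poly[ic, ]; b <- poly[inx, ]
      cr <- cross2(o, a, b)
      if (cr <= 0) next  # reflex or degenerate corner
      # no other active vertex inside the candidate ear
      others <- setdiff(idx, c(ip, ic, inx))
      if (length(others) > 0) {
        P <- poly[others, , drop = FALSE]
        s1 <- (a[1]-o[1])*(P[,2]-o[2]) - (a[2]-o[2])*(P[,1]-o[1])
        s2 <- (b[1]-a[1])*(P[,2]-a[2]) - (b[2]-a[2])*(P[,1]-a[1])
        s3 <- (o[1]-b[1])*(P[,2]-b[2]) - (o[2]-b[2])*(P[,1]-b[1])
        if (any(s1 >= 0 & s2 >= 0 & s3 >= 0)) next
      }
      tris <- rbind(tris, c(ip, ic, inx))
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # numerically stubborn corner: clip the most convex one regardless
      best <- which.max(vapply(seq_along(idx), function(i) {
        m <- length(idx)
        cross2(poly[idx[if (i == 1) m else i - 1], ], poly[idx[i], ],
               poly[idx[if (i == m) 1 else i + 1], ])
      }, 0))
      m <- length(idx)
      tris <- rbind(tris, c(idx[if (best == 1) m else best - 1], idx[best],
                            idx[if (best == m) 1 else best + 1]))
      idx <- idx[-best]
    }
  }
  rbind(tris, idx)
}

polyset_triangles <- function(polys) {
  out <- lapply(polys, function(p) {
    p <- as.matrix(p)
    t_ <- earcut(p)
    cbind(p[t_[, 1], 1], p[t_[, 1], 2], p[t_[, 2], 1], p[t_[, 2], 2],
          p[t_[, 3], 1], p[t_[, 3], 2])
  })
  do.call(rbind, out)
}

polyset_area <- function(polys) {
  sum(vapply(polys, function(p) abs(signed_area(as.matrix(p))), 0))
}

has_self_intersection <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (length(js) == 0) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (p2[1]-p1[1])*(q1[,2]-p1[2]) - (p2[2]-p1[2])*(q1[,1]-p1[1])
  d2 <- (p2[1]-p1[1])*(q2[,2]-p1[2]) - (p2[2]-p1[2])*(q2[,1]-p1[1])
  d3 <- (q2[,1]-q1[,1])*(p1[2]-q1[,2]) - (q2[,2]-q1[,2])*(p1[1]-q1[,1])
  d4 <- (q2[,1]-q1[,1])*(p2[2]-q1[,2]) - (q2[,2]-q1[,2])*(p2[1]-q1[,1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Dice and Jaccard overlap of two polygonal regions
#'
#' Areas are computed by exact polygon clipping: each simple polygon is
#' triangulated by ear clipping and the intersection area is accumulated
#' over convex triangle-triangle clips, so the scores are deterministic
#' and resolution-free. Both arguments may be sets of disjoint polygons
#' (e.g. separate chambers on one plane).
#'
#' \deqn{D = 2 |Re \cap Tr| / (|Re| + |Tr|), \quad
#'       J = |Re \cap Tr| / |Re \cup Tr|}
#' The identity J = D / (2 - D) holds to machine precision.
#'
#' @param re,tr polygon (k x 2 matrix) or list of polygons, mm.
#' @return named list with `dice`, `jaccard` and the three areas.
#' @export
overlap_scores <- function(re, tr) {
  if (is.matrix(re) || is.data.frame(re)) re <- list(re)
  if (is.matrix(tr) || is.data.frame(tr)) tr <- list(tr)
  for (p in c(re, tr))
    if (has_self_intersection(p))
      stop_lheart("lheart_invalid_region", "self-intersecting polygon")
  if (length(re) == 0 || length(tr) == 0 ||
      polyset_area(re) == 0 || polyset_area(tr) == 0)
    return(list(dice = 0, jaccard = 0, area_re = polyset_area(re),
                area_tr = polyset_area(tr), area_intersection = 0))
  a_re <- polyset_area(re)
  a_tr <- polyset_area(tr)
  inter <- cpp_tri_overlap_area(polyset_triangles(re), polyset_triangles(tr))
  inter <- min(inter, a_re, a_tr)
  dice <- 2 * inter / (a_re + a_tr)
  jac <- inter / (a_re + a_tr - inter)
  list(dice = dice, jaccard = jac, area_re = a_re, area_tr = a_tr,
       area_intersection = inter)
}

# resample a closed polyline at a fixed arc-length step (for curve-based
# Hausdorff between contours)
densify_polyline <- function(p, step = 0.5) {
  p <- as.matrix(p)
  n <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- max(1L, ceiling(seg[i] / step))
    t_ <- (seq_len(k) - 1) / k
    j <- if (i == n) 1 else i + 1
    out[[i]] <- outer(1 - t_, p[i, ]) + outer(t_, p[j, ])
  }
  do.call(rbind, out)
}

#' Validate a reconstruction against reference contours
#'
#' For each long-axis plane of the reference study, the reconstructed
#' surface is cut by the plane ([intersect_mesh_plane()]) and the section
#' is compared with the union of the reference chamber regions delineated
#' on that plane: Hausdorff distance between the densely resampled
#' boundary curves (0.5 mm arc step), and Dice/Jaccard overlap of the
#' enclosed regions. A Dice of 0.7 or more is flagged as adequate overlap.
#'
#' @param surface a watertight [tri_surface()].
#' @param study the reference `contour_study` supplying the long-axis
#'   contours and plane metadata.
#' @param views views to validate against (default: the long-axis views).
#' @return data.frame with one row per plane (`plane_id`, `view`,
#'   `hausdorff_mm`, `dice`, `jaccard`, `adequate`) plus attribute
#'   `means` (named vector of across-plane averages).
#' @export
validate_study <- function(surface, study,
                           views = c("2ch", "3ch", "4ch")) {
  stopifnot(inherits(surface, "tri_surface"),
            inherits(study, "contour_study"))
  plane_views <- vapply(study$planes, `[[`, "", "view")
  planes <- study$planes[plane_views %in% views]
  if (length(planes) == 0)
    stop_lheart("lheart_parameter_error",
                "study has no planes in the requested views")
  rows <- list()
  for (meta in planes) {
    cts <- Filter(function(ct) ct$plane_id == meta$plane_id, study$contours)
    if (length(cts) == 0) next
    # reference regions in physical in-plane mm
    tr_polys <- lapply(cts, function(ct)
      cbind(ct$points[, 1] * meta$spacing[1], ct$points[, 2] * meta$spacing[2]))
    re_polys <- intersect_mesh_plane(surface, meta)
    if (length(re_polys) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        plane_id = meta$plane_id, view = meta$view, hausdorff_mm = NA_real_,
        dice = 0, jaccard = 0, adequate = FALSE)
      next
    }
    ov <- overlap_scores(re_polys, tr_polys)
    re_pts <- do.call(rbind, lapply(re_polys, densify_polyline))
    tr_pts <- do.call(rbind, lapply(tr_polys, densify_polyline))
    h <- hausdorff(re_pts, tr_pts)
    rows[[length(rows) + 1]] <- data.frame(
      plane_id = meta$plane_id, view = meta$view, hausdorff_mm = h,
      dice = ov$dice, jaccard = ov$jaccard, adequate = ov$dice >= 0.7)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "means") <- c(hausdorff_mm = mean(out$hausdorff_mm, na.rm = TRUE),
                          dice = mean(out$dice), jaccard = mean(out$jaccard))
  out
}
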