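#' Auxiliary grid points for tetrahedral meshing
#'
#' A regular lattice with spacing `h` covering the axis-aligned bounding
#' box of the point cloud expanded by `expand` per side. Lattice points
#' closer than `h/2` to any cloud point are removed (they would duplicate
#' data points in the mesh).
#'
#' @param cloud n x 3 point matrix (mm).
#' @param h lattice spacing, mm.
#' @param expand fractional bounding-box expansion per side.
#' @param cap maximum number of lattice points before removal.
#' @return matrix of lattice points.
#' @export
auxiliary_grid <- function(cloud, h, expand = 0.1, cap = 2e6) {
  cloud <- as_point_matrix(cloud)
  if (nrow(cloud) == 0 || !is.numeric(h) || h <= 0)
    stop_lheart("lheart_parameter_error",
                "need a non-empty cloud and positive spacing")
  lo <- apply(cloud, 2, min)
  hi <- apply(cloud, 2, max)
  mid <- (lo + hi) / 2
  span <- pmax(hi - lo, h)  # degenerate boxes get one cell of thickness
  lo <- mid - (0.5 + expand) * span
  hi <- mid + (0.5 + expand) * span
  # lattice anchored at absolute multiples of h (translation-invariant:
  # nearly identical clouds see identical auxiliary points)
  axes <- lapply(1:3, function(j)
    seq(floor(lo[j] / h) * h, ceiling(hi[j] / h) * h, by = h))
  n_total <- prod(lengths(axes))
  if (n_total > cap)
    stop_lheart("lheart_resolution_cap", sprintf(
      "grid spacing %g mm would generate %g lattice points (cap %g)",
      h, n_total, cap))
  q <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  dimnames(q) <- NULL
  keep <- cpp_nn(q, cloud)$dist >= h / 2
  q[keep, , drop = FALSE]
}

#' Delaunay tetrahedral mesh of a point set
#'
#' Incremental Delaunay tetrahedralization of the combined contour cloud
#' and auxiliary grid. All input points become mesh vertices (exact
#' duplicates are removed first); the union of tets is the convex hull of
#' the input. Face adjacency between tets and the hull boundary faces are
#' precomputed.
#'
#' @param points n x 3 matrix, at least 5 non-coplanar points.
#' @return A `tet_mesh`: `vertices`, `tets` (m x 4), `volumes` (mm^3),
#'   `faces` (f x 3 vertex triples), `face_tets` (f x 2, second column 0
#'   for hull boundary faces), `boundary_tets` (indices of tets with at
#'   least one hull face).
#' @export
tetrahedralize <- function(points) {
  points <- as_point_matrix(points)
  points <- points[!duplicated(points), , drop = FALSE]
  if (nrow(points) < 5)
    stop_lheart("lheart_degenerate_input",
                "tetrahedralization needs >= 5 distinct points")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop_lheart("lheart_degenerate_input", "input points are coplanar")
  tets <- cpp_delaunay3d(points)$tets
  v <- points
  a <- v[tets[, 1], ]; b <- v[tets[, 2], ]; c3 <- v[tets[, 3], ]
  d <- v[tets[, 4], ]
  u <- b - a; w <- c3 - a; z <- d - a
  vol <- abs(u[, 1] * (w[, 2] * z[, 3] - w[, 3] * z[, 2]) -
             u[, 2] * (w[, 1] * z[, 3] - w[, 3] * z[, 1]) +
             u[, 3] * (w[, 1] * z[, 2] - w[, 2] * z[, 1])) / 6
  # exactly coplanar inputs (points of one imaging slice) can yield flat
  # sliver tets; they carry ~zero volume but are combinatorially required
  # for a conforming mesh, so they are kept

  nt <- nrow(tets)
  # the 4 faces of each tet, sorted triples for matching
  fidx <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  fsort <- t(apply(fidx, 1, sort))
  key <- paste(fsort[, 1], fsort[, 2], fsort[, 3])
  owner <- rep(seq_len(nt), 4)
  first <- match(key, key)
  is_first <- first == seq_along(key)
  pair <- integer(length(key))
  pair[!is_first] <- owner[first[!is_first]]
  faces <- fsort[is_first, , drop = FALSE]
  face_tets <- cbind(owner[is_first], 0L)
  # fill second tet for interior faces
  second_of <- setNames(owner[!is_first], key[!is_first])
  m2 <- match(key[is_first], key[!is_first])
  face_tets[, 2] <- ifelse(is.na(m2), 0L, owner[!is_first][m2])
  boundary_tets <- sort(unique(face_tets[face_tets[, 2] == 0L, 1]))

  structure(list(vertices = points, tets = tets, volumes = vol,
                 faces = faces, face_tets = face_tets,
                 boundary_tets = boundary_tets),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh: %d vertices, %d tets, %d faces (%d on hull)>\n",
              nrow(x$vertices), nrow(x$tets), nrow(x$faces),
              sum(x$face_tets[, 2] == 0)))
  invisible(x)
}

face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(area = triangle_areas(v, f),
       centroid = (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                   v[f[, 3], , drop = FALSE]) / 3)
}

#' Face weights of the distance-weighted minimal-surface energy
#'
#' Discretises \eqn{E(S) = \int_S d(x, C) \, dA} with one piecewise-constant
#' quadrature element per triangular face:
#' `weight = Area(face) * d(centroid(face), cloud)`.
#'
#' @param mesh a `tet_mesh`.
#' @param cloud the contour point cloud the surface should hug.
#' @return numeric vector of non-negative weights, one per mesh face.
#' @export
face_weights <- function(mesh, cloud) {
  stopifnot(inherits(mesh, "tet_mesh"))
  g <- face_geometry(mesh)
  g$area * cpp_nn(g$centroid, as_point_matrix(cloud))$dist
}

#' Seed tets for the graph-cut boundary conditions
#'
#' Source (interior) seeds are the tets of the blood-pool core: every tet
#' whose centroid falls, at its slice level, inside the per-level contour
#' polygon shrunk by `margin` about the polygon centroid. Endocardial
#' sections are star-shaped about their centroid in practice, so the
#' shrunken polygons are guaranteed-inside regions; seeding the whole core
#' (rather than isolated centroid points) is what prevents the
#' distance-weighted minimal surface from collapsing onto a finite seed
#' set. The per-level centroids themselves are additionally located and
#' must land in non-boundary tets. Sink (exterior) seeds are all tets with
#' at least one face on the convex-hull boundary.
#'
#' Closed contours that are not part of any interpolated stack - the
#' merged bifurcation sections - bound blood pool just the same, so their
#' shrunken interiors seed the cut as well (via `extra_polygons`); without
#' them the energy prefers to cap the three chambers and drop the
#' junction.
#'
#' @param mesh a `tet_mesh`.
#' @param matrices list of `contour_matrix` objects.
#' @param margin polygon shrink factor in (0, 1).
#' @param extra_polygons list of lists with elements `points` (closed n x 3
#'   polygon), `normal` and `slab` (half-thickness, mm): additional
#'   guaranteed-inside cross-sections (e.g. merged bifurcation contours).
#' @return list with integer vectors `source` and `sink` (disjoint).
#' @export
select_seeds <- function(mesh, matrices, margin = 0.85,
                         extra_polygons = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  anchors <- do.call(rbind, lapply(matrices, matrix_row_centroids))
  if (is.null(anchors) || nrow(anchors) == 0)
    stop_lheart("lheart_parameter_error", "no anchor points available")
  loc <- cpp_locate_points(mesh$vertices, mesh$tets, anchors)
  if (any(loc == 0))
    stop_lheart("lheart_seed_conflict", sprintf(
      "%d interior anchor(s) could not be located in the mesh",
      sum(loc == 0)))
  snk <- mesh$boundary_tets
  conflict <- intersect(unique(loc), snk)
  if (length(conflict) > 0)
    stop_lheart("lheart_seed_conflict", sprintf(
      "%d anchor(s) fall in hull-boundary tets; the auxiliary grid is too coarse",
      length(conflict)))

  v <- mesh$vertices
  tc <- (v[mesh$tets[, 1], ] + v[mesh$tets[, 2], ] +
         v[mesh$tets[, 3], ] + v[mesh$tets[, 4], ]) / 4
  src <- logical(nrow(mesh$tets))
  src[loc] <- TRUE
  seed_slab <- function(poly3, nrm, level, slab) {
    basis <- plane_basis(nrm)
    lev_tc <- as.vector(tc %*% nrm)
    cand <- which(abs(lev_tc - level) <= slab & !src)
    if (length(cand) == 0) return(invisible())
    ctr <- colMeans(poly3)
    poly3 <- sweep(poly3, 2, ctr) * margin
    poly3 <- sweep(poly3, 2, ctr, `+`)
    inside <- point_in_poly((tc %*% t(basis))[cand, , drop = FALSE],
                            poly3 %*% t(basis))
    src[cand[inside]] <<- TRUE
  }
  for (cm in matrices) {
    dl <- if (length(cm$levels) > 1) max(diff(cm$levels)) else 1
    for (i in seq_along(cm$levels))
      seed_slab(cm$points[i, , ], cm$normal,
                cm$levels[i], dl / 2)
  }
  for (pg in extra_polygons)
    seed_slab(as_point_matrix(pg$points), pg$normal,
              mean(as_point_matrix(pg$points) %*% pg$normal), pg$slab)
  src[snk] <- FALSE
  src[loc] <- TRUE
  list(source = which(src), sink = snk)
}

#' Minimum-cut segmentation of the tetrahedral mesh
#'
#' Builds an s-t graph with one node per tet, undirected capacity equal to
#' the face weight on every interior face, and effectively infinite links
#' from the terminals to the seed tets, then solves max-flow/min-cut. The
#' returned interior/exterior labelling attains the global minimum of the
#' discretised surface energy subject to the seeds; `cut_cost` is the sum
#' of face weights across the interface.
#'
#' @param mesh a `tet_mesh`.
#' @param weights per-face weights from [face_weights()].
#' @param seeds seed list from [select_seeds()].
#' @return A `cut_labeling`: logical vector `interior` (per tet) plus
#'   `cut_cost`.
#' @export
min_cut <- function(mesh, weights, seeds) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nt <- nrow(mesh$tets)
  if (length(weights) != nrow(mesh$faces))
    stop_lheart("lheart_parameter_error", "one weight per face required")
  if (length(seeds$source) == 0 || length(seeds$sink) == 0 ||
      length(intersect(seeds$source, seeds$sink)) > 0)
    stop_lheart("lheart_parameter_error",
                "seeds must be non-empty and disjoint")
  interior_face <- mesh$face_tets[, 2] != 0L
  ft <- mesh$face_tets[interior_face, , drop = FALSE]
  w <- weights[interior_face]
  big <- 2 * sum(w) + 1
  s_node <- nt + 1L
  t_node <- nt + 2L
  edges <- rbind(ft,
                 cbind(rep(s_node, length(seeds$source)), seeds$source),
                 cbind(seeds$sink, rep(t_node, length(seeds$sink))))
  caps <- c(w, rep(big, length(seeds$source) + length(seeds$sink)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nt + 2 - igraph::vcount(g)))
  mf <- igraph::max_flow(g, source = s_node, target = t_node, capacity = caps)
  interior <- rep(FALSE, nt)
  part1 <- as.integer(mf$partition1)
  if (s_node %in% part1) interior[part1[part1 <= nt]] <- TRUE
  else {
    part2 <- as.integer(mf$partition2)
    interior[part2[part2 <= nt]] <- TRUE
  }
  # isolated non-seed components have no path to either terminal;
  # they fall wherever the solver left them, with zero-cost interfaces
  cut_faces <- interior[ft[, 1]] != interior[ft[, 2]]
  cut_cost <- sum(w[cut_faces])
  if (abs(cut_cost - mf$value) > 1e-6 * max(1, mf$value) &&
      mf$value < big)
    warn_lheart("lheart_cut_mismatch", sprintf(
      "cut bookkeeping (%.6g) differs from max-flow value (%.6g)",
      cut_cost, mf$value))
  structure(list(interior = interior, cut_cost = cut_cost,
                 flow_value = mf$value), class = "cut_labeling")
}

#' Extract the interface surface of a cut labelling
#'
#' The reconstructed surface consists of every mesh face whose two
#' incident tets carry different labels (hull faces of interior tets are
#' included with the exterior side implicit). Faces are oriented outward:
#' the interior tet lies on the negative side of each triangle normal.
#' Non-manifold edge junctions (interior tets meeting only along an edge)
#' are repaired by relabelling the cheapest offending tet.
#'
#' @param mesh a `tet_mesh`.
#' @param labeling a `cut_labeling` from [min_cut()].
#' @return A [tri_surface()] with attribute `interior_volume`, the summed
#'   volume of interior tets (equals the enclosed surface volume).
#' @export
extract_surface <- function(mesh, labeling) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(labeling, "cut_labeling"))
  interior <- labeling$interior
  for (attempt in 1:60) {
    res <- try_extract(mesh, interior)
    if (!is.null(res$surface)) {
      attr(res$surface, "interior_volume") <- sum(mesh$volumes[interior])
      attr(res$surface, "interior") <- interior
      return(res$surface)
    }
    fix <- res$repair_tet
    if (is.null(fix)) break
    interior[fix] <- !interior[fix]
  }
  stop_lheart("lheart_nonmanifold",
              "could not repair non-manifold cut interface")
}

try_extract <- function(mesh, interior) {
  ft <- mesh$face_tets
  t2 <- ft[, 2]
  lab1 <- interior[ft[, 1]]
  lab2 <- ifelse(t2 == 0L, FALSE, interior[pmax(t2, 1L)])
  on_surf <- lab1 != lab2
  faces <- mesh$faces[on_surf, , drop = FALSE]
  if (nrow(faces) == 0)
    return(list(surface = tri_surface(mesh$vertices, faces)))

  # edge-manifold check first: interior regions meeting only along an edge
  # put that edge on 4 extracted faces; relabelling the cheapest incident
  # tet resolves the junction
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ekey)
  if (any(tab != 2)) {
    bad_v <- unique(as.integer(unlist(strsplit(names(tab)[tab != 2], " "))))
    touch_count <- rowSums(matrix(mesh$tets %in% bad_v, nrow(mesh$tets), 4))
    touches <- which(interior & touch_count >= 2)
    if (length(touches) == 0) touches <- which(!interior & touch_count >= 2)
    if (length(touches) > 0)
      return(list(surface = NULL,
                  repair_tet = touches[which.min(mesh$volumes[touches])]))
    return(list(surface = NULL, repair_tet = NULL))
  }

  # per-face outward vote from the interior tet's opposite vertex; flat
  # sliver tets vote unreliably, so the vote only fixes the global sign
  # after combinatorial orientation propagation
  int_tet <- ifelse(lab1[on_surf], ft[on_surf, 1], t2[on_surf])
  opp <- opposite_vertex(mesh, int_tet, faces)
  v <- mesh$vertices
  n_ <- cross_rows(v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE],
                   v[faces[, 3], , drop = FALSE] - v[faces[, 1], , drop = FALSE])
  cen <- (v[faces[, 1], , drop = FALSE] + v[faces[, 2], , drop = FALSE] +
          v[faces[, 3], , drop = FALSE]) / 3
  vote <- rowSums(n_ * (v[opp, , drop = FALSE] - cen))
  faces <- orient_faces(faces, vote)
  if (is.null(faces)) return(list(surface = NULL, repair_tet = NULL))

  surf <- compact_surface(mesh$vertices, faces)
  if (is_watertight(surf)) return(list(surface = surf))
  list(surface = NULL, repair_tet = NULL)
}

# propagate a consistent orientation across each connected component of a
# closed triangle set (every edge on exactly 2 faces); flip each component
# so the summed outward `vote` (normal pointing away from the interior) is
# positive. Returns NULL when the face set is not edge-manifold.
orient_faces <- function(faces, vote) {
  nf <- nrow(faces)
  ekeys <- matrix("", nf, 3)
  for (e in 1:3) {
    a <- faces[, e]; b <- faces[, if (e == 3) 1 else e + 1]
    ekeys[, e] <- paste(pmin(a, b), pmax(a, b))
  }
  face_of_edge <- split(rep(seq_len(nf), 3), as.vector(ekeys))
  if (any(lengths(face_of_edge) != 2)) return(NULL)
  flipped <- rep(FALSE, nf)
  seen <- rep(FALSE, nf)
  for (root in seq_len(nf)) {
    if (seen[root]) next
    comp <- integer(0)
    queue <- root
    seen[root] <- TRUE
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, i)
      fi <- if (flipped[i]) faces[i, c(1, 3, 2)] else faces[i, ]
      dir_i <- rbind(fi[1:2], fi[2:3], fi[c(3, 1)])
      for (e in 1:3) {
        nbrs <- face_of_edge[[ekeys[i, e]]]
        j <- nbrs[nbrs != i]
        if (length(j) != 1 || seen[j]) next
        # j must traverse the shared edge in the opposite direction
        key_ab <- dir_i[if (flipped[i]) 4 - e else e, ]
        fj <- faces[j, ]
        dir_j <- rbind(fj[1:2], fj[2:3], fj[c(3, 1)])
        same <- any(dir_j[, 1] == key_ab[1] & dir_j[, 2] == key_ab[2])
        flipped[j] <- same  # same direction means j needs a flip
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
    sgn <- sum(ifelse(flipped[comp], -vote[comp], vote[comp]))
    if (sgn > 0) flipped[comp] <- !flipped[comp]
  }
  faces[flipped, ] <- faces[flipped, c(1, 3, 2), drop = FALSE]
  faces
}

opposite_vertex <- function(mesh, tet_idx, faces) {
  tt <- mesh$tets[tet_idx, , drop = FALSE]
  out <- integer(nrow(faces))
  for (c_ in 1:4) {
    cand <- tt[, c_]
    is_opp <- cand != faces[, 1] & cand != faces[, 2] & cand != faces[, 3]
    out[is_opp & out == 0L] <- cand[is_opp & out == 0L]
  }
  out
}

cross_rows <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

# drop unused vertices, remember original indices
compact_surface <- function(vertices, faces) {
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  s <- tri_surface(vertices[used, , drop = FALSE],
                   matrix(remap[faces], ncol = 3))
  attr(s, "orig_index") <- used
  s
}

#' Reconstruct a surface from a densified contour cloud
#'
#' Convenience wrapper chaining [auxiliary_grid()], [tetrahedralize()],
#' [face_weights()], [select_seeds()], [min_cut()] and
#' [extract_surface()].
#'
#' @param cloud full contour point cloud (densified short-axis groups,
#'   registered long-axis points, bifurcation contour points).
#' @param matrices densified `contour_matrix` list (for the interior
#'   anchors).
#' @param h auxiliary grid spacing, mm; default is the median point spacing
#'   of the cloud's nearest neighbours.
#' @param expand,cap passed to [auxiliary_grid()].
#' @param extra_polygons passed to [select_seeds()].
#' @return A [tri_surface()]; diagnostics in attribute `recon_info`.
#' @export
reconstruct_surface <- function(cloud, matrices, h = NULL, expand = 0.1,
                                cap = 2e6, extra_polygons = NULL) {
  cloud <- as_point_matrix(cloud)
  if (is.null(h)) {
    med <- median(vapply(seq_len(min(nrow(cloud), 1000)), function(i) {
      d <- sqrt(colSums((t(cloud[-i, , drop = FALSE]) - cloud[i, ])^2))
      min(d)
    }, 0))
    h <- max(1, 2 * med)
  }
  q <- auxiliary_grid(cloud, h, expand = expand, cap = cap)
  mesh <- tetrahedralize(rbind(cloud, q))
  w <- face_weights(mesh, cloud)
  seeds <- select_seeds(mesh, matrices, extra_polygons = extra_polygons)
  lab <- min_cut(mesh, w, seeds)
  surf <- extract_surface(mesh, lab)
  attr(surf, "recon_info") <- list(
    h = h, n_cloud = nrow(cloud), n_grid = nrow(q),
    n_tets = nrow(mesh$tets), n_interior = sum(lab$interior),
    cut_cost = lab$cut_cost)
  surf
}
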