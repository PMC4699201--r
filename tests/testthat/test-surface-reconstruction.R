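test_that("the auxiliary grid covers the cloud without duplicating it", {
  # unit-cube corners, h = 0.5: closed-form lattice count minus removals
  # (lattice runs over multiples of h covering the 10%-expanded box)
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  q <- auxiliary_grid(corners, 0.5, expand = 0.1)
  ax <- seq(floor(-0.1 / 0.5) * 0.5, ceiling(1.1 / 0.5) * 0.5, by = 0.5)
  removed <- sum(lheart:::cpp_nn(as.matrix(expand.grid(ax, ax, ax)),
                                 corners)$dist < 0.25)
  expect_equal(nrow(q), length(ax)^3 - removed)
  # translation invariance of the lattice: shifting the cloud by exactly
  # h moves the grid by exactly h
  q2 <- auxiliary_grid(sweep(corners, 2, c(0.5, 0, 0), `+`), 0.5,
                       expand = 0.1)
  expect_equal(sweep(q2, 2, c(0.5, 0, 0)), q)
  # contract: no grid point within h/2 of the cloud
  expect_true(all(lheart:::cpp_nn(q, corners)$dist >= 0.25))

  # degenerate single-point cloud still yields a non-empty grid
  q1 <- auxiliary_grid(matrix(c(1, 2, 3), 1), 1)
  expect_gt(nrow(q1), 0)

  expect_error(auxiliary_grid(corners, 1e-4, cap = 1e5),
               class = "lheart_resolution_cap")
})

test_that("Delaunay tetrahedralization is conforming and fills the hull", {
  # minimal case: triangular bipyramid -> 2 tets
  bi <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
              c(0.5, 0.4, 1), c(0.5, 0.4, -1))
  m <- tetrahedralize(bi)
  expect_equal(nrow(m$tets), 2)

  set.seed(51)
  pts <- matrix(rnorm(900, sd = 10), ncol = 3)
  mesh <- tetrahedralize(pts)
  # every input point is a mesh vertex
  expect_equal(nrow(mesh$vertices), 300)
  # interior faces pair exactly two tets; the rest lie on the hull
  expect_true(all(mesh$face_tets[, 1] > 0))
  n_on_hull <- sum(mesh$face_tets[, 2] == 0)
  expect_equal(4 * nrow(mesh$tets),
               n_on_hull + 2 * (nrow(mesh$faces) - n_on_hull))
  # union of tets = convex hull: total volume matches the hull volume
  # computed independently as tetra fans from an interior point
  hull_faces <- mesh$faces[mesh$face_tets[, 2] == 0, ]
  o <- colMeans(mesh$vertices)
  hull_vol <- sum(vapply(seq_len(nrow(hull_faces)), function(i) {
    a <- mesh$vertices[hull_faces[i, 1], ] - o
    b <- mesh$vertices[hull_faces[i, 2], ] - o
    c_ <- mesh$vertices[hull_faces[i, 3], ] - o
    abs(det(rbind(a, b, c_))) / 6
  }, 0))
  expect_equal(sum(mesh$volumes), hull_vol, tolerance = 1e-9)

  # Delaunay property: empty circumsphere on a sample of tets
  for (i in sample(nrow(mesh$tets), 50)) {
    t_ <- mesh$tets[i, ]
    A <- mesh$vertices[t_, ]
    M <- 2 * sweep(A[2:4, ], 2, A[1, ])
    cc <- tryCatch(solve(M, rowSums(A[2:4, ]^2) - sum(A[1, ]^2)),
                   error = function(e) NULL)
    if (is.null(cc)) next
    r <- sqrt(sum((A[1, ] - cc)^2))
    d <- sqrt(colSums((t(mesh$vertices) - cc)^2))
    d[t_] <- Inf
    expect_gt(min(d) - r, -1e-7 * r)
  }

  expect_error(tetrahedralize(cbind(runif(10), runif(10), 0)),
               class = "lheart_degenerate_input")
})

test_that("face weights discretise the distance-weighted area element", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  mesh <- tetrahedralize(v)
  # single-point cloud at a face centroid gives that face weight zero
  g <- lheart:::face_geometry(mesh)
  cloud <- g$centroid[3, , drop = FALSE]
  w <- face_weights(mesh, cloud)
  expect_equal(w[3], 0)
  expect_true(all(w >= 0))

  # closed form: unit right triangle at distance 2 from a one-point cloud
  tri_mesh <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   faces = rbind(c(1L, 2L, 3L)))
  class(tri_mesh) <- "tet_mesh"
  w1 <- face_weights(tri_mesh, rbind(c(1 / 3, 1 / 3, 2)))
  expect_equal(w1, 0.5 * 2)

  # oracle: linear-scan nearest distance at centroids
  set.seed(52)
  cloud2 <- matrix(runif(90, -2, 2), ncol = 3)
  w2 <- face_weights(mesh, cloud2)
  d_brute <- brute_nn_dist(g$centroid, cloud2)
  expect_equal(w2, g$area * d_brute, tolerance = 1e-12)
})

test_that("seed selection separates blood pool from hull", {
  ph <- phantom_fixture()
  cl <- project_study(ph$study)
  sax <- lheart:::sax_contour_list(ph$study)
  dens <- densify_groups(sax, n = 24)
  cloud <- dens$points
  q <- auxiliary_grid(cloud, 8)
  mesh <- tetrahedralize(rbind(cloud, q))
  seeds <- select_seeds(mesh, dens$matrices)
  expect_gt(length(seeds$source), 0)
  expect_equal(length(intersect(seeds$source, seeds$sink)), 0)
  # sink equals an independent boundary-face scan
  ft <- mesh$face_tets
  expect_identical(seeds$sink, sort(unique(ft[ft[, 2] == 0, 1])))
  # every per-level centroid is located inside exactly one tet
  anchors <- do.call(rbind, lapply(dens$matrices,
                                   lheart:::matrix_row_centroids))
  loc <- lheart:::cpp_locate_points(mesh$vertices, mesh$tets, anchors)
  expect_true(all(loc > 0))
})

test_that("graph min-cut attains the exhaustive optimum on small meshes", {
  # forced cut through the single shared face of a 2-tet mesh
  bi <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
              c(0.5, 0.4, 1), c(0.5, 0.4, -1))
  mesh2 <- tetrahedralize(bi)
  w2 <- face_weights(mesh2, rbind(c(10, 10, 10)))
  seeds2 <- list(source = 1L, sink = 2L)
  cut2 <- min_cut(mesh2, w2, seeds2)
  shared <- which(mesh2$face_tets[, 2] != 0)
  expect_equal(cut2$cut_cost, w2[shared])

  set.seed(53)
  n_match <- 0
  for (rep in 1:25) {
    pts <- matrix(runif(24, 0, 10), ncol = 3)
    mesh <- tryCatch(tetrahedralize(pts), error = function(e) NULL)
    if (is.null(mesh) || nrow(mesh$tets) > 15) next
    w <- runif(nrow(mesh$faces), 0.1, 5)
    nt <- nrow(mesh$tets)
    seeds <- list(source = 1L, sink = nt)
    if (nt < 3) next
    cut <- min_cut(mesh, w, seeds)
    expect_equal(cut$cut_cost, brute_min_cut(mesh, w, seeds),
                 tolerance = 1e-9)
    # scale equivariance: doubling weights doubles the cost
    cut2x <- min_cut(mesh, 2 * w, seeds)
    expect_equal(cut2x$cut_cost, 2 * cut$cut_cost, tolerance = 1e-9)
    expect_identical(cut2x$interior, cut$interior)
    n_match <- n_match + 1
  }
  expect_gte(n_match, 10)
})

test_that("extracted surfaces book-keep energy and volume exactly", {
  ph <- phantom_fixture()
  sax <- lheart:::sax_contour_list(ph$study)
  dens <- densify_groups(sax, n = 24)
  cl <- project_study(ph$study)
  cloud <- rbind(dens$points, cl$points[cl$view != "sax", ])
  extra <- lapply(dens$merged, function(p)
    list(points = p, normal = c(0, 0, 1), slab = 4))
  q <- auxiliary_grid(cloud, 7)
  mesh <- tetrahedralize(rbind(cloud, q))
  w <- face_weights(mesh, cloud)
  seeds <- select_seeds(mesh, dens$matrices, extra_polygons = extra)
  lab <- min_cut(mesh, w, seeds)
  surf <- extract_surface(mesh, lab)

  expect_true(is_watertight(surf))
  ft <- mesh$face_tets
  # energy bookkeeping: cut cost equals the summed weights over the
  # interface faces of the min-cut labelling
  lab_cut <- ifelse(ft[, 2] == 0, FALSE, lab$interior[pmax(ft[, 2], 1)])
  on_cut <- lab$interior[ft[, 1]] != lab_cut
  expect_equal(lab$cut_cost, sum(w[on_cut & ft[, 2] != 0]), tolerance = 1e-9)
  # every extracted face separates differently-labelled tets (post-repair)
  interior <- attr(surf, "interior")
  lab2 <- ifelse(ft[, 2] == 0, FALSE, interior[pmax(ft[, 2], 1)])
  on_surf <- interior[ft[, 1]] != lab2
  expect_equal(nrow(surf$triangles), sum(on_surf))
  # enclosed volume equals the summed interior tet volumes
  expect_equal(surface_volume(surf), sum(mesh$volumes[interior]),
               tolerance = 1e-9 * sum(mesh$volumes[interior]))
})
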