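test_that("mesh-plane intersection recovers analytic sections", {
  cube <- make_cube_surface(1)
  polys <- intersect_mesh_plane(cube, axial_plane(z = 0.5))
  expect_length(polys, 1)
  expect_equal(abs(signed_area(polys[[1]])), 1, tolerance = 1e-9)

  # sphere cut at offset c: circle of radius sqrt(r^2 - c^2)
  sph <- make_icosphere(3, 30)
  for (off in c(0, 12, 25)) {
    ps <- intersect_mesh_plane(sph, axial_plane(z = off))
    expect_length(ps, 1)
    r_true <- sqrt(30^2 - off^2)
    expect_equal(abs(signed_area(ps[[1]])), pi * r_true^2,
                 tolerance = 0.01 * pi * r_true^2)
  }

  expect_length(intersect_mesh_plane(sph, axial_plane(z = 99)), 0)

  open <- sph
  z1 <- open$vertices[open$triangles[, 1], 3]
  z2 <- open$vertices[open$triangles[, 2], 3]
  z3 <- open$vertices[open$triangles[, 3], 3]
  crossing <- which(pmin(z1, z2, z3) < 0 & pmax(z1, z2, z3) > 0)
  open$triangles <- open$triangles[-crossing[1:3], ]
  expect_error(intersect_mesh_plane(open, axial_plane(z = 0)),
               class = "lheart_open_intersection")
})

test_that("Hausdorff distance matches the brute-force double loop", {
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  set.seed(71)
  for (rep in 1:5) {
    x <- matrix(rnorm(400), ncol = 2)
    y <- matrix(rnorm(400, mean = 0.5), ncol = 2)
    expect_equal(hausdorff(x, y), brute_hausdorff(cbind(x, 0), cbind(y, 0)))
    expect_identical(hausdorff(x, y), hausdorff(y, x))  # symmetric
  }
  x3 <- matrix(rnorm(300), ncol = 3)
  expect_equal(hausdorff(x3, x3), 0)
  expect_error(hausdorff(x3, matrix(0, 0, 3)),
               class = "lheart_undefined_distance")
})

test_that("Dice and Jaccard follow their closed forms and identity", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ov <- overlap_scores(sq, sq)
  expect_equal(ov$dice, 1)
  expect_equal(ov$jaccard, 1)

  # two unit squares overlapping in a 0.5 x 1 strip
  sq2 <- sq
  sq2[, 1] <- sq2[, 1] + 0.5
  ov2 <- overlap_scores(sq, sq2)
  expect_equal(ov2$dice, 0.5, tolerance = 1e-12)
  expect_equal(ov2$jaccard, 1 / 3, tolerance = 1e-12)
  # swapping the regions leaves the scores unchanged
  ov2b <- overlap_scores(sq2, sq)
  expect_equal(ov2b$dice, ov2$dice)

  # J = D / (2 - D) to machine precision; Monte-Carlo area oracle
  set.seed(72)
  for (rep in 1:5) {
    a <- circle_points(17, r = runif(1, 0.5, 1.5))
    b <- circle_points(23, r = runif(1, 0.5, 1.5),
                       cx = runif(1, -0.5, 0.5), cy = runif(1, -0.5, 0.5))
    ov3 <- overlap_scores(a, b)
    expect_equal(ov3$jaccard, ov3$dice / (2 - ov3$dice), tolerance = 1e-12)
    ns <- 2e5
    smp <- cbind(runif(ns, -3, 3), runif(ns, -3, 3))
    in_a <- lheart:::point_in_poly(smp, a)
    in_b <- lheart:::point_in_poly(smp, b)
    mc <- mean(in_a & in_b) * 36
    se <- sqrt(mc * (36 - mc) / ns)
    expect_lt(abs(ov3$area_intersection - mc), 4 * se + 1e-6)
  }

  # monotone: translating one region away never raises the overlap
  prev <- 1
  for (dx in seq(0, 2, 0.25)) {
    d_ <- overlap_scores(sq, sweep(sq, 2, c(dx, 0), `+`))$dice
    expect_lte(d_, prev + 1e-12)
    prev <- d_
  }

  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(overlap_scores(bow, sq), class = "lheart_invalid_region")
})

test_that("study validation scores sections against reference contours", {
  # reference compared against an extrusion of itself: D = J = 1, H ~ 0
  r <- 14
  poly <- circle_points(72, r = r)
  planes <- list(axial_plane(0, "pz", "sax"),
                 plane_meta(position = c(0, 0, 0), row_dir = c(1, 0, 0),
                            col_dir = c(0, 0, 1), spacing = c(1, 1),
                            plane_id = "cut2ch", view = "2ch"))
  # a cylinder surface whose 2ch section is a 2r x 30 rectangle
  th <- seq(0, 2 * pi, length.out = 73)[1:72]
  rings <- lapply(seq(-15, 15, 1.5), function(z)
    cbind(r * cos(th), r * sin(th), z))
  nlev <- length(rings)
  v <- do.call(rbind, rings)
  f <- list()
  for (i in seq_len(nlev - 1)) {
    base <- (i - 1) * 72
    for (j in seq_len(72)) {
      jn <- if (j == 72) 1 else j + 1
      f[[length(f) + 1]] <- rbind(
        c(base + j, base + jn, base + 72 + j),
        c(base + jn, base + 72 + jn, base + 72 + j))
    }
  }
  # cap with fans
  v <- rbind(v, c(0, 0, -15), c(0, 0, 15))
  bot <- nrow(v) - 1; top <- nrow(v)
  for (j in seq_len(72)) {
    jn <- if (j == 72) 1 else j + 1
    f[[length(f) + 1]] <- rbind(c(j, bot, jn),
                                c((nlev - 1) * 72 + j, (nlev - 1) * 72 + jn,
                                  top))
  }
  cyl <- tri_surface(v, do.call(rbind, f))
  if (surface_volume(cyl) < 0) cyl$triangles <- cyl$triangles[, c(1, 3, 2)]
  expect_true(is_watertight(cyl))

  # the 2ch reference: the true rectangular section in pixel coordinates
  rect <- rbind(c(-r, -15), c(r, -15), c(r, 15), c(-r, 15))
  study <- contour_study(
    list(contour2d(rect, "LV", "cut2ch"),
         contour2d(circle_points(36, r), "LV", "pz")),
    planes)
  val <- validate_study(cyl, study)
  expect_equal(nrow(val), 1)  # only the long-axis plane is scored
  expect_gt(val$dice, 0.99)
  expect_gt(val$jaccard, 0.98)
  expect_lt(val$hausdorff_mm, 0.5)
  expect_true(val$adequate)
  expect_equal(val$jaccard, val$dice / (2 - val$dice), tolerance = 1e-12)
})
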