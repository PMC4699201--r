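test_that("signed area and re-orientation follow the shoelace convention", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(signed_area(sq), 1)
  expect_equal(signed_area(sq[4:1, ]), -1)

  # oracle: triangulation-fan area sum on a random simple (star) polygon
  set.seed(41)
  for (rep in 1:5) {
    r <- runif(12, 1, 3)
    th <- sort(runif(12, 0, 2 * pi))
    poly <- cbind(r * cos(th), r * sin(th))
    fan <- sum(vapply(2:11, function(i) {
      a <- poly[1, ]; b <- poly[i, ]; c_ <- poly[i + 1, ]
      ((b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])) / 2
    }, 0))
    expect_equal(signed_area(poly), fan, tolerance = 1e-12)
  }

  ccw <- reorient_ccw(sq[4:1, ])
  expect_gt(signed_area(ccw), 0)
  expect_equal(sort(ccw[, 1] + 10 * ccw[, 2]), sort(sq[, 1] + 10 * sq[, 2]))
  expect_identical(reorient_ccw(ccw), ccw)  # idempotent
  expect_error(signed_area(rbind(c(0, 0), c(1, 1))),
               class = "lheart_degenerate_contour")

  # 3D: sign is defined about the reference normal
  sq3 <- cbind(sq, 0)
  expect_gt(signed_area(sq3, c(0, 0, 1)), 0)
  expect_lt(signed_area(sq3, c(0, 0, -1)), 0)
})

test_that("closed-contour PCHIP resampling interpolates its knots", {
  set.seed(42)
  poly <- circle_points(16, r = 20)
  r16 <- resample_contour(poly, 16)
  # uniform chord lengths on a circle: original parameters are resampled
  expect_equal(r16, poly, tolerance = 1e-9)
  expect_identical(nrow(resample_contour(poly, 55)), 55L)
  expect_equal(resample_contour(poly, 55)[1, ], poly[1, ])

  # analytic circle oracle: the PCHIP curve through 12 points of a
  # 30 mm circle deviates at most 0.2366 mm from the radius (frozen from
  # an independent PCHIP evaluation of the same chord-length scheme)
  r48 <- resample_contour(circle_points(12, r = 30), 48)
  expect_lt(max(abs(sqrt(rowSums(r48^2)) - 30)), 0.24)
  # with knots at the delineation density the error is well under 0.5%
  r96 <- resample_contour(circle_points(24, r = 30), 96)
  expect_lt(max(abs(sqrt(rowSums(r96^2)) - 30)), 0.005 * 30)

  expect_error(resample_contour(poly, 3), class = "lheart_parameter_error")
})

test_that("circular-shift matching equals the exhaustive scan", {
  set.seed(43)
  ref <- circle_points(24, r = 15) + matrix(rnorm(48, sd = 0.5), ncol = 2)
  rolled <- ref[((seq_len(24) - 1 + 7) %% 24) + 1, ]
  expect_equal(as.integer(match_contours(ref, rolled)),
               as.integer((24 - 7) %% 24))
  k <- as.integer(match_contours(ref, rolled))
  expect_equal(lheart:::apply_shift(rolled, k), ref)
  expect_identical(as.integer(match_contours(ref, ref)), 0L)

  for (rep in 1:5) {
    other <- circle_points(24, r = 15, phase = runif(1, 0, 2 * pi)) +
      matrix(rnorm(48, sd = 0.3), ncol = 2)
    scan <- vapply(0:23, function(k)
      mean(sqrt(rowSums((ref - lheart:::apply_shift(other, k))^2))), 0)
    expect_identical(as.integer(match_contours(ref, other)),
                     as.integer(which.min(scan) - 1L))
  }
  expect_error(match_contours(ref, ref[1:10, ]),
               class = "lheart_parameter_error")
})

test_that("contour matrices track correspondences up the stack", {
  circ3d <- function(n, r, z, phase = 0)
    cbind(circle_points(n, r, phase = phase), z)
  stack <- lapply(c(0, 8, 16), function(z) circ3d(24, 20, z))
  cm <- build_matrix(stack, c(0, 8, 16), n = 24)
  expect_identical(dim(cm$points), c(3L, 24L, 3L))
  # identical circles: columns are vertical lines
  for (j in c(1, 7, 13))
    expect_lt(max(dist(cm$points[, j, 1:2])), 1e-9)

  # one rotated circle: matching realises the per-pair exhaustive minimum
  stack2 <- list(circ3d(24, 20, 0), circ3d(24, 20, 8, phase = 5 * pi / 12),
                 circ3d(24, 20, 16, phase = 5 * pi / 12))
  cm2 <- build_matrix(stack2, c(0, 8, 16), n = 24)
  mean_adj <- mean(sqrt(rowSums((cm2$points[2, , ] - cm2$points[1, , ])^2)))
  scan <- vapply(0:23, function(k) {
    a <- resample_contour(reorient_ccw(stack2[[1]], c(0, 0, 1)), 24)
    b <- resample_contour(reorient_ccw(stack2[[2]], c(0, 0, 1)), 24)
    mean(sqrt(rowSums((a - lheart:::apply_shift(b, k))^2)))
  }, 0)
  expect_equal(mean_adj, min(scan), tolerance = 1e-9)

  expect_error(build_matrix(stack, c(0, 0, 16), n = 24),
               class = "lheart_ambiguous_stack")
  expect_error(build_matrix(stack[1], 0, n = 24),
               class = "lheart_parameter_error")
})

test_that("level interpolation reproduces knots and analytic shapes", {
  circ3d <- function(n, r, z) cbind(circle_points(n, r), z)
  stack <- lapply(seq(0, 32, 8), function(z) circ3d(24, 25 + z / 4, z))
  cm <- build_matrix(stack, seq(0, 32, 8), n = 24)

  same <- interpolate_levels(cm, dim(cm$points)[1])
  expect_equal(same$points, cm$points, tolerance = 1e-9)

  # two-level column tracks are linear: midpoint is the average
  cm2 <- build_matrix(stack[c(1, 5)], c(0, 32), n = 24)
  mid <- interpolate_levels(cm2, 3)
  expect_equal(mid$points[2, , ], (cm2$points[1, , ] + cm2$points[2, , ]) / 2,
               tolerance = 1e-12)

  # cone phantom: interpolated points stay within 0.5% of the true radius
  dense <- interpolate_levels(cm, 33)
  r_true <- 25 + dense$levels / 4
  r_got <- sqrt(dense$points[, , 1]^2 + dense$points[, , 2]^2)
  expect_lt(max(abs(r_got - r_true) / r_true), 0.005)
  # no extrapolation outside the level range
  expect_gte(min(dense$levels), min(cm$levels))
  expect_lte(max(dense$levels), max(cm$levels))

  expect_error(interpolate_levels(cm, 3), class = "lheart_parameter_error")
})

test_that("group densification preserves the bifurcation gap", {
  circ3d <- function(n, r, z, cx = 0) cbind(circle_points(n, r, cx = cx), z)
  sax <- c(
    lapply(seq(0, 24, 8), function(z)
      list(points = circ3d(20, 25, z), label = "LV")),
    list(list(points = circ3d(30, 30, 32), label = "MERGED")),
    lapply(seq(40, 56, 8), function(z)
      list(points = circ3d(16, 12, z, cx = -10), label = "LA")),
    lapply(seq(40, 56, 8), function(z)
      list(points = circ3d(12, 8, z, cx = 15), label = "AO")))
  dens <- densify_groups(sax, n = 24)
  expect_named(dens$matrices, c("LV", "LA", "AO"))
  # conservation: densified point count is sum over groups of M x N
  n_dense <- sum(vapply(dens$matrices, function(m) prod(dim(m$points)[1:2]), 0))
  expect_equal(nrow(dens$points), n_dense + nrow(dens$passthrough))
  # the gap between the LV top and the LA/AO bottom is never interpolated
  z <- dens$points[seq_len(n_dense), 3]
  expect_equal(sum(z > 24 + 1e-9 & z < 40 - 1e-9), 0)
  # merged contour points pass through unchanged
  expect_equal(dens$passthrough, circ3d(30, 30, 32))

  # a study with a single-contour group passes it through with a warning
  expect_warning(
    d2 <- densify_groups(sax[c(1:5, 6)], n = 24),
    class = "lheart_sparse_group")
  expect_false("LA" %in% names(d2$matrices))
})
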