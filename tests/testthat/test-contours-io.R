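test_that("planar contours project into patient coordinates", {
  m <- axial_plane()
  expect_equal(project_contour_to_3d(rbind(c(0, 0)), m)[1, ], c(0, 0, 0))

  m2 <- plane_meta(position = c(5, 5, 5), row_dir = c(0, 1, 0),
                   col_dir = c(0, 0, 1), spacing = c(1.43, 1.43))
  expect_equal(project_contour_to_3d(rbind(c(10, 20)), m2)[1, ],
               c(5, 5 + 14.3, 5 + 28.6))

  # oracle: explicit 4x4 homogeneous matrix applied point-wise
  set.seed(11)
  for (rep in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    w <- rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    m3 <- plane_meta(position = rnorm(3, sd = 30), row_dir = u, col_dir = w,
                     spacing = runif(2, 0.5, 2))
    uv <- matrix(runif(40, 0, 100), ncol = 2)
    M <- rbind(cbind(u * m3$spacing[1], w * m3$spacing[2], 0, m3$position),
               c(0, 0, 0, 1))
    expected <- t(M %*% rbind(uv[, 1], uv[, 2], 0, 1))[, 1:3]
    got <- project_contour_to_3d(uv, m3)
    expect_equal(got, expected, tolerance = 1e-12)
    # projected points stay on the plane and preserve scaled distances
    nrm <- lheart:::plane_normal(m3)
    expect_lt(max(abs((got %*% nrm) - sum(nrm * m3$position))), 1e-9)
  }
})

test_that("isotropic projection preserves in-plane distances", {
  m <- plane_meta(position = c(1, 2, 3),
                  row_dir = c(1, 1, 0) / sqrt(2),
                  col_dir = c(0, 0, 1), spacing = c(1.37, 1.37))
  uv <- matrix(runif(30, 0, 50), ncol = 2)
  p3 <- project_contour_to_3d(uv, m)
  d2 <- as.matrix(dist(uv)) * 1.37
  d3 <- as.matrix(dist(p3))
  expect_lt(max(abs(d2 - d3)), 1e-9)
})

test_that("plane metadata is validated and extracted from DICOM fields", {
  m <- extract_plane_meta(list(ImagePositionPatient = c(0, 0, 0),
                               ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
                               PixelSpacing = c(1, 1)))
  expect_equal(m$row_dir, c(1, 0, 0))
  expect_equal(m$col_dir, c(0, 1, 0))

  # PixelSpacing is (row, col) spacing; u advances along columns
  m2 <- extract_plane_meta(list(ImagePositionPatient = c(0, 0, 0),
                                ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
                                PixelSpacing = c(2, 0.5)))
  expect_equal(m2$spacing, c(0.5, 2))

  expect_error(
    extract_plane_meta(list(ImagePositionPatient = c(0, 0, 0),
                            ImageOrientationPatient = c(2, 0, 0, 0, 1, 0),
                            PixelSpacing = c(1, 1))),
    class = "lheart_invalid_metadata")
  expect_error(
    extract_plane_meta(list(ImagePositionPatient = c(0, 0, 0),
                            PixelSpacing = c(1, 1))),
    regexp = "0020,0037", class = "lheart_missing_metadata")
  expect_error(
    plane_meta(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1)),
    class = "lheart_invalid_metadata")
})

test_that("study files round-trip through JSON", {
  ph <- phantom_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_study(ph$study, path)
  back <- read_study(path)
  expect_equal(length(back$contours), length(ph$study$contours))
  expect_equal(names(back$planes), names(ph$study$planes))
  for (i in seq_along(back$contours)) {
    expect_equal(back$contours[[i]]$points, ph$study$contours[[i]]$points)
    expect_equal(back$contours[[i]]$label, ph$study$contours[[i]]$label)
  }
  # second write is byte-identical (determinism of the serialisation)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_study(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty study is valid
  p3 <- withr::local_tempfile(fileext = ".json")
  write_study(contour_study(list(), ph$study$planes["sax_05"]), p3)
  expect_equal(length(read_study(p3)$contours), 0)

  # dangling plane reference is a referential-integrity error
  expect_error(
    contour_study(list(contour2d(circle_points(8), "LV", "nope")),
                  ph$study$planes["sax_05"]),
    class = "lheart_referential_integrity")
})

test_that("meshes round-trip through PLY, OFF and STL", {
  s <- regular_tet_surface()
  for (fmt in c("ply", "off", "stl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(s, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 4)
    expect_equal(nrow(back$triangles), 4)
    expect_equal(sort(as.vector(back$vertices)), sort(as.vector(s$vertices)))
    expect_equal(abs(surface_volume(back)), abs(surface_volume(s)),
                 tolerance = 1e-12)
  }
  # binary PLY round-trips coordinates exactly
  ico <- make_icosphere(1, 17.3)
  pb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(ico, pb, binary = TRUE)
  back <- read_mesh(pb)
  expect_identical(back$vertices, ico$vertices)
  expect_identical(back$triangles, ico$triangles)
})

test_that("open surfaces are refused with offending edges named", {
  s <- regular_tet_surface()
  s$triangles <- s$triangles[-1, , drop = FALSE]  # punch a hole
  path <- withr::local_tempfile(fileext = ".ply")
  expect_error(write_mesh(s, path), regexp = "edge",
               class = "lheart_nonmanifold")
})
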