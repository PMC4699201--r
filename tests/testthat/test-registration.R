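test_that("rigid transforms form a group and act as isometries", {
  set.seed(21)
  p <- matrix(rnorm(90, sd = 20), ncol = 3)
  for (rep in 1:10) {
    tr <- random_rigid(30, 20)
    q <- apply_rigid(tr, p)
    # isometry: pairwise distance matrix preserved
    expect_lt(max(abs(as.matrix(dist(p)) - as.matrix(dist(q)))), 1e-9)
    # group property: t^-1 t = identity
    expect_lt(max(abs(apply_rigid(invert_rigid(tr), q) - p)), 1e-9)
  }
  expect_equal(apply_rigid(rigid_transform(), p), p)
  # orthonormality maintained under long composition chains
  acc <- rigid_transform()
  for (rep in 1:200) acc <- compose_rigid(acc, random_rigid(10, 1))
  expect_lt(max(abs(crossprod(acc$rotation) - diag(3))), 1e-9)
  expect_lt(abs(det(acc$rotation) - 1), 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)),
               class = "lheart_parameter_error")
})

test_that("mutual subset filtering satisfies its defining properties", {
  set.seed(22)
  for (rep in 1:10) {
    cx <- matrix(runif(600, 0, 50), ncol = 3)
    cy <- matrix(runif(600, 20, 70), ncol = 3)
    dh <- hausdorff(cx, cy)

    # property 2: epsilon at least the Hausdorff distance removes nothing
    full <- mutual_subset(cx, cy, dh * 1.0001)
    expect_true(all(full$x_keep) && all(full$y_keep))

    eps1 <- dh * 0.35
    eps2 <- dh * 0.55
    s1 <- tryCatch(mutual_subset(cx, cy, eps1), error = function(e) NULL)
    s2 <- mutual_subset(cx, cy, eps2)
    # property 1: filtered subsets are within epsilon in Hausdorff distance
    expect_lte(hausdorff(s2$x_sub, s2$y_sub), eps2)
    if (!is.null(s1)) {
      expect_lte(hausdorff(s1$x_sub, s1$y_sub), eps1)
      # property 3: monotone in epsilon
      expect_true(all(!s1$x_keep | s2$x_keep))
      expect_true(all(!s1$y_keep | s2$y_keep))
      # termination bound: one point removed per non-final sweep
      expect_lte(s1$iterations, nrow(cx) + nrow(cy))
    }
  }
})

test_that("mutual subset matches the naive fixed-point oracle", {
  set.seed(23)
  for (rep in 1:8) {
    cx <- matrix(runif(240, 0, 30), ncol = 3)
    cy <- matrix(runif(240, 10, 40), ncol = 3)
    eps <- runif(1, 4, 12)
    got <- tryCatch(mutual_subset(cx, cy, eps), error = function(e) NULL)
    want <- naive_mutual_subset(cx, cy, eps)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_identical(got$x_keep, want$x_keep)
      expect_identical(got$y_keep, want$y_keep)
    }
  }
  expect_error(mutual_subset(matrix(0, 1, 3), matrix(10, 1, 3), 1),
               class = "lheart_epsilon_too_small")
})

test_that("ICP recovers exact rigid motions from one-to-one points", {
  set.seed(24)
  ref <- matrix(rnorm(150, sd = 25), ncol = 3)
  expect_equal(unclass(icp_rigid(ref, ref))$rotation, diag(3),
               tolerance = 1e-9)
  for (rep in 1:10) {
    tr <- random_rigid(5, 5)
    moving <- apply_rigid(tr, ref)
    rec <- icp_rigid(ref, moving)
    tru <- invert_rigid(tr)
    expect_lt(max(abs(rec$rotation - tru$rotation)), 1e-6)
    expect_lt(max(abs(rec$translation - tru$translation)), 1e-6)
    # objective history is non-increasing
    h <- attr(rec, "history")
    expect_true(all(diff(h) <= 1e-9))
    expect_lte(h[length(h)], h[1])
  }
  line <- cbind(seq_len(10), seq_len(10) * 2, seq_len(10) * -1)
  expect_error(icp_rigid(ref, line), class = "lheart_degenerate_geometry")
})

test_that("registering an already-aligned cloud stays within sampling slack", {
  # with a continuous long-axis curve matched against discrete short-axis
  # rings 8 mm apart, point-to-point ICP slides tangentially along the
  # surface; on aligned data the residual motion is bounded by the slice
  # sampling and the cloud stays on the endocardial surface
  ph <- phantom_fixture()
  f <- implicit_shape(ph$spec)
  cl <- project_study(ph$study)
  sax <- cl$points[cl$view == "sax", ]
  for (v in c("2ch", "4ch")) {
    lax <- cl$points[cl$view == v, ]
    res <- register_pair(sax, lax)
    ang <- acos(min(1, (sum(diag(res$transform$rotation)) - 1) / 2)) * 180 / pi
    expect_lt(ang, 5)
    expect_lt(sqrt(sum(res$transform$translation^2)), 5)
    moved <- apply_rigid(res$transform, lax)
    expect_lt(mean(abs(f(moved))), 1.5)
  }
  expect_error(register_pair(sax, cl$points[cl$view == "3ch", ], alpha = 0.6),
               class = "lheart_parameter_error")
})

test_that("alpha-subsets are nested and registration moves points back to the surface", {
  ph <- phantom_fixture()
  f <- implicit_shape(ph$spec)
  pert <- perturb_study(ph$study, 5, 5, seed = 7)
  cl <- project_study(pert$study)
  sax <- cl$points[cl$view == "sax", ]
  lax <- cl$points[cl$view == "2ch", ]

  dh <- hausdorff(sax, lax)
  s_small <- mutual_subset(sax, lax, 0.2 * dh)
  s_large <- mutual_subset(sax, lax, 0.5 * dh)
  expect_true(all(!s_small$x_keep | s_large$x_keep))
  expect_true(all(!s_small$y_keep | s_large$y_keep))

  res <- register_pair(sax, lax)
  moved <- apply_rigid(res$transform, lax)
  expect_lt(mean(abs(f(moved))), mean(abs(f(lax))))
  # the ICP objective (RMS to the reference subset) improves
  sub <- mutual_subset(sax, lax, res$diagnostics$epsilon)
  rms_pre <- sqrt(mean(lheart:::nn_dist(sub$y_sub, sub$x_sub)^2))
  expect_lt(res$diagnostics$rms, rms_pre)
})

test_that("study registration treats the three pairs independently", {
  ph <- phantom_fixture()
  pert1 <- perturb_study(ph$study, 4, 4, seed = 31)
  cl1 <- project_study(pert1$study)
  reg1 <- register_study(cl1)

  # cloud sizes conserved, sax never moved
  expect_equal(nrow(reg1$cloud$points), nrow(cl1$points))
  expect_identical(reg1$cloud$points[cl1$view == "sax", ],
                   cl1$points[cl1$view == "sax", ])

  # changing only the 4ch perturbation leaves the 2ch transform unchanged
  st2 <- pert1$study
  extra <- perturb_study(ph$study, 5, 5, seed = 99)
  st2$planes[["lax_4ch"]] <- extra$study$planes[["lax_4ch"]]
  reg2 <- register_study(project_study(st2))
  expect_equal(reg1$transforms[["2ch"]]$rotation,
               reg2$transforms[["2ch"]]$rotation, tolerance = 1e-12)
  expect_equal(reg1$transforms[["2ch"]]$translation,
               reg2$transforms[["2ch"]]$translation, tolerance = 1e-12)
  expect_gt(max(abs(reg1$transforms[["4ch"]]$translation -
                    reg2$transforms[["4ch"]]$translation)), 1e-6)
})
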