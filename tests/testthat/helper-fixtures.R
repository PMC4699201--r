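# shared fixtures and independent oracles, built in code

# icosphere: subdivided icosahedron scaled to the requested radius
make_icosphere <- function(subdiv = 2, radius = 1) {
  t_ <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t_, 0), c(1, t_, 0), c(-1, -t_, 0), c(1, -t_, 0),
    c(0, -1, t_), c(0, 1, t_), c(0, -1, -t_), c(0, 1, -t_),
    c(t_, 0, -1), c(t_, 0, 1), c(-t_, 0, -1), c(-t_, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(5, 12, 3), c(3, 11, 7), c(7, 8, 9), c(9, 2, 10))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!exists(k, envir = mid_cache, inherits = FALSE)) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        assign(k, nrow(v), envir = mid_cache)
      }
      get(k, envir = mid_cache)
    }
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  s <- tri_surface(v, f)
  if (surface_volume(s) < 0) s$triangles <- s$triangles[, c(1, 3, 2)]
  s
}

# axis-aligned unit cube surface (12 triangles, outward orientation)
make_cube_surface <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  s <- tri_surface(v, f)
  if (surface_volume(s) < 0) s$triangles <- s$triangles[, c(1, 3, 2)]
  s
}

regular_tet_surface <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tri_surface(v, f)
}

axial_plane <- function(z = 0, plane_id = "p", view = "sax", spacing = 1) {
  plane_meta(position = c(0, 0, z), row_dir = c(1, 0, 0),
             col_dir = c(0, 1, 0), spacing = c(spacing, spacing),
             plane_id = plane_id, view = view)
}

circle_points <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

edge_lengths_of <- function(s) {
  f <- s$triangles
  e <- cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(paste(a, b))
  sqrt(rowSums((s$vertices[a[keep], , drop = FALSE] -
                s$vertices[b[keep], , drop = FALSE])^2))
}

# --- independent oracles ------------------------------------------------

brute_nn_dist <- function(x, y) {
  apply(x, 1, function(p) min(sqrt(colSums((t(y) - p)^2))))
}

brute_hausdorff <- function(x, y) {
  max(max(brute_nn_dist(x, y)), max(brute_nn_dist(y, x)))
}

# naive re-scan-until-stable mutual subset filter
naive_mutual_subset <- function(cx, cy, eps) {
  kx <- rep(TRUE, nrow(cx)); ky <- rep(TRUE, nrow(cy))
  repeat {
    changed <- FALSE
    for (i in which(kx))
      if (min(sqrt(colSums((t(cy[ky, , drop = FALSE]) - cx[i, ])^2))) > eps) {
        kx[i] <- FALSE; changed <- TRUE
      }
    if (!any(kx)) return(NULL)
    for (i in which(ky))
      if (min(sqrt(colSums((t(cx[kx, , drop = FALSE]) - cy[i, ])^2))) > eps) {
        ky[i] <- FALSE; changed <- TRUE
      }
    if (!any(ky)) return(NULL)
    if (!changed) break
  }
  list(x_keep = kx, y_keep = ky)
}

random_rigid <- function(max_deg = 5, max_mm = 5) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  t_ <- rnorm(3); t_ <- t_ / sqrt(sum(t_^2)) * runif(1, 0, max_mm)
  rigid_transform(R, t_)
}

# exhaustive minimum cut over all labelings consistent with the seeds
brute_min_cut <- function(mesh, w, seeds) {
  nt <- nrow(mesh$tets)
  interior_face <- mesh$face_tets[, 2] != 0
  ft <- mesh$face_tets[interior_face, , drop = FALSE]
  wi <- w[interior_face]
  free <- setdiff(seq_len(nt), c(seeds$source, seeds$sink))
  base <- rep(FALSE, nt)
  base[seeds$source] <- TRUE
  if (length(free) == 0) {
    return(sum(wi[base[ft[, 1]] != base[ft[, 2]]]))
  }
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free))))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    lab <- base
    lab[free] <- combos[i, ]
    cost <- sum(wi[lab[ft[, 1]] != lab[ft[, 2]]])
    if (cost < best) best <- cost
  }
  best
}

# one default phantom study per test file, built lazily
.fixture_env <- new.env()
phantom_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$spec <- phantom_spec()
    .fixture_env$study <- slice_study(.fixture_env$spec)
  }
  list(spec = .fixture_env$spec, study = .fixture_env$study)
}

# a small, fast pipeline configuration for repeated reconstructions
fast_config <- function() {
  pipeline_config(interp = list(N = 32), recon = list(h_mm = 6),
                  post = list(remesh = FALSE))
}

phantom_recon_fast <- function() {
  if (is.null(.fixture_env$recon)) {
    ph <- phantom_fixture()
    .fixture_env$recon <- reconstruct_study(ph$study, fast_config())
  }
  .fixture_env$recon
}
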