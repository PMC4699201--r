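vertex_adjacency <- function(surface) {
  e <- surface_edges(surface)
  # undirected unique edges
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(k), , drop = FALSE]
  list(edges = e, from = c(e[, 1], e[, 2]), to = c(e[, 2], e[, 1]))
}

laplacian_step <- function(v, adj, factor) {
  nb_sum <- rowsum(v[adj$to, , drop = FALSE], adj$from)
  deg <- as.vector(rowsum(rep(1, length(adj$from)), adj$from))
  idx <- as.integer(rownames(nb_sum))
  delta <- v
  delta[] <- 0
  delta[idx, ] <- nb_sum / deg - v[idx, , drop = FALSE]
  v + factor * delta
}

#' Taubin band-pass surface smoothing
#'
#' Alternates a positive (`lambda`) and a negative (`mu`) umbrella
#' Laplacian step per iteration. Unlike plain Laplacian smoothing the
#' negative step compensates the shrinkage, so enclosed volume is
#' approximately preserved (< 2% change at the defaults). Connectivity is
#' never altered.
#'
#' @param surface a watertight [tri_surface()].
#' @param iterations number of lambda/mu passes.
#' @param lambda positive smoothing factor in (0, 1).
#' @param mu negative inflation factor, `mu < -lambda`.
#' @return the smoothed [tri_surface()].
#' @export
smooth_taubin <- function(surface, iterations = 10, lambda = 0.5,
                          mu = -0.53) {
  check_watertight(surface, "smooth_taubin")
  if (!(lambda > 0 && lambda < 1) || !(mu < -lambda))
    stop_lheart("lheart_parameter_error",
                "need 0 < lambda < 1 and mu < -lambda")
  if (iterations == 0) return(surface)
  adj <- vertex_adjacency(surface)
  v <- surface$vertices
  for (i in seq_len(iterations)) {
    v <- laplacian_step(v, adj, lambda)
    v <- laplacian_step(v, adj, mu)
  }
  tri_surface(v, surface$triangles)
}

#' Isotropic remeshing
#'
#' Repeated passes of edge split (edges longer than 4/3 of the target),
#' edge collapse (shorter than 4/5 of the target, guarded by the link
#' condition), valence-improving edge flips and tangential Laplacian
#' relaxation, with vertices projected back onto the input surface after
#' each pass. Produces a watertight mesh whose median edge length
#' approaches `target_edge` while staying within `target_edge/2` Hausdorff
#' distance of the input.
#'
#' @param surface a watertight [tri_surface()].
#' @param target_edge desired edge length, mm; must not exceed a quarter
#'   of the bounding-box diagonal.
#' @param passes number of remeshing passes.
#' @return the remeshed [tri_surface()].
#' @export
remesh_isotropic <- function(surface, target_edge, passes = 5) {
  check_watertight(surface, "remesh_isotropic")
  diag_len <- vnorm(apply(surface$vertices, 2, max) -
                    apply(surface$vertices, 2, min))
  if (!is.numeric(target_edge) || target_edge <= 0 ||
      target_edge > diag_len / 4)
    stop_lheart("lheart_parameter_error", sprintf(
      "target_edge must be in (0, %.2f] mm", diag_len / 4))
  ref_v <- surface$vertices
  ref_f <- surface$triangles
  v <- surface$vertices
  f <- surface$triangles
  for (p in seq_len(passes)) {
    sp <- split_long_edges(v, f, 4 / 3 * target_edge)
    v <- sp$v; f <- sp$f
    cl <- collapse_short_edges(v, f, 4 / 5 * target_edge,
                               4 / 3 * target_edge)
    v <- cl$v; f <- cl$f
    fl <- flip_for_valence(v, f)
    f <- fl$f
    v <- tangential_relax(v, f)
    v <- cpp_project_points(v, ref_v, ref_f)$closest
  }
  tri_surface(v, f)
}

edge_list_unique <- function(f) {
  e <- cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  k <- paste(a, b)
  keep <- !duplicated(k)
  cbind(a[keep], b[keep])
}

split_long_edges <- function(v, f, max_len) {
  e <- edge_list_unique(f)
  len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                       v[e[, 2], , drop = FALSE])^2))
  long <- e[len > max_len, , drop = FALSE]
  if (nrow(long) == 0) return(list(v = v, f = f))
  mid <- (v[long[, 1], , drop = FALSE] + v[long[, 2], , drop = FALSE]) / 2
  mid_id <- nrow(v) + seq_len(nrow(long))
  v <- rbind(v, mid)
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(nrow(long)))
    assign(paste(long[i, 1], long[i, 2]), mid_id[i], envir = lookup)
  get_mid <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (exists(k, envir = lookup, inherits = FALSE))
      get(k, envir = lookup) else 0L
  }
  out <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    tr <- f[i, ]
    m12 <- get_mid(tr[1], tr[2]); m23 <- get_mid(tr[2], tr[3])
    m31 <- get_mid(tr[3], tr[1])
    ms <- c(m12, m23, m31)
    ns <- sum(ms > 0)
    out[[i]] <- if (ns == 0) matrix(tr, 1) else
    if (ns == 3) rbind(c(tr[1], m12, m31), c(tr[2], m23, m12),
                       c(tr[3], m31, m23), c(m12, m23, m31)) else
    if (ns == 1) {
      if (m12 > 0) rbind(c(tr[1], m12, tr[3]), c(m12, tr[2], tr[3]))
      else if (m23 > 0) rbind(c(tr[1], tr[2], m23), c(tr[1], m23, tr[3]))
      else rbind(c(tr[1], tr[2], m31), c(m31, tr[2], tr[3]))
    } else {  # two split edges: fan from the vertex between them
      if (m12 > 0 && m23 > 0)
        rbind(c(tr[2], m23, m12), c(tr[1], m12, m23), c(tr[1], m23, tr[3]))
      else if (m23 > 0 && m31 > 0)
        rbind(c(tr[3], m31, m23), c(tr[2], m23, m31), c(tr[2], m31, tr[1]))
      else
        rbind(c(tr[1], m12, m31), c(tr[3], m31, m12), c(tr[3], m12, tr[2]))
    }
  }
  list(v = v, f = do.call(rbind, out))
}

vertex_neighbors <- function(f, nv) {
  e <- edge_list_unique(f)
  nb <- vector("list", nv)
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  nb
}

collapse_short_edges <- function(v, f, min_len, max_len) {
  e <- edge_list_unique(f)
  len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                       v[e[, 2], , drop = FALSE])^2))
  ord <- order(len)
  nb <- vertex_neighbors(f, nrow(v))
  locked <- rep(FALSE, nrow(v))
  remap <- seq_len(nrow(v))
  newpos <- v
  for (i in ord) {
    if (len[i] >= min_len) break
    a <- e[i, 1]; b <- e[i, 2]
    if (locked[a] || locked[b]) next
    # link condition: shared neighbours must be exactly the two wing tips
    shared <- intersect(nb[[a]], nb[[b]])
    if (length(shared) != 2) next
    mid <- (v[a, ] + v[b, ]) / 2
    # avoid creating overlong edges
    cand <- setdiff(union(nb[[a]], nb[[b]]), c(a, b))
    if (any(sqrt(colSums((t(v[cand, , drop = FALSE]) - mid)^2)) > max_len))
      next
    remap[b] <- a
    newpos[a, ] <- mid
    locked[c(a, b, cand)] <- TRUE
  }
  if (all(remap == seq_along(remap))) return(list(v = v, f = f))
  f2 <- matrix(remap[f], ncol = 3)
  degen <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  f2 <- f2[!degen, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  newid <- integer(nrow(v))
  newid[used] <- seq_along(used)
  list(v = newpos[used, , drop = FALSE], f = matrix(newid[f2], ncol = 3))
}

flip_for_valence <- function(v, f) {
  # target valence 6 on a closed surface; flip when it reduces total
  # squared deviation and keeps the mesh valid
  nv <- nrow(v)
  val <- tabulate(as.vector(f), nv)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]), ekey(f[, 3], f[, 1]))
  face_of_edge <- split(rep(seq_len(nrow(f)), 3), ek)
  edge_exists <- new.env(hash = TRUE)
  for (k in unique(ek)) assign(k, TRUE, envir = edge_exists)
  changed_faces <- rep(FALSE, nrow(f))
  for (k in names(face_of_edge)) {
    fs <- face_of_edge[[k]]
    if (length(fs) != 2 || any(changed_faces[fs])) next
    ab <- as.integer(strsplit(k, " ")[[1]])
    t1 <- f[fs[1], ]; t2 <- f[fs[2], ]
    c1 <- setdiff(t1, ab); c2 <- setdiff(t2, ab)
    if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
    if (exists(ekey(c1, c2), envir = edge_exists, inherits = FALSE)) next
    dev <- function(x) (x - 6)^2
    gain <- (dev(val[ab[1]]) + dev(val[ab[2]]) + dev(val[c1]) + dev(val[c2])) -
            (dev(val[ab[1]] - 1) + dev(val[ab[2]] - 1) +
             dev(val[c1] + 1) + dev(val[c2] + 1))
    if (gain <= 0) next
    # rebuild the two triangles around the flipped diagonal, preserving
    # orientation; a precedes b in t1's traversal
    pos_a <- which(t1 == ab[1]); pos_b <- which(t1 == ab[2])
    a_first <- (pos_b - pos_a) %% 3 == 1
    a <- if (a_first) ab[1] else ab[2]
    b <- if (a_first) ab[2] else ab[1]
    f[fs[1], ] <- c(a, c2, c1)
    f[fs[2], ] <- c(c2, b, c1)
    val[a] <- val[a] - 1L; val[b] <- val[b] - 1L
    val[c1] <- val[c1] + 1L; val[c2] <- val[c2] + 1L
    changed_faces[fs] <- TRUE
    assign(ekey(c1, c2), TRUE, envir = edge_exists)
  }
  list(f = f)
}

tangential_relax <- function(v, f, factor = 0.5) {
  s <- tri_surface(v, f)
  adj <- vertex_adjacency(s)
  nb_sum <- rowsum(v[adj$to, , drop = FALSE], adj$from)
  deg <- as.vector(rowsum(rep(1, length(adj$from)), adj$from))
  idx <- as.integer(rownames(nb_sum))
  target <- v
  target[idx, ] <- nb_sum / deg
  # vertex normals (area-weighted)
  n_f <- cross_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                    v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  vn <- matrix(0, nrow(v), 3)
  for (c_ in 1:3) {
    acc <- rowsum(n_f, f[, c_])
    vn[as.integer(rownames(acc)), ] <- vn[as.integer(rownames(acc)), ] + acc
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn <- vn / nrm
  d <- target - v
  d_tan <- d - vn * rowSums(d * vn)
  v + factor * d_tan
}
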