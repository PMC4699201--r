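#' Pipeline configuration
#'
#' Builds the full configuration for [reconstruct_study()], merging user
#' overrides into the defaults. Unknown keys are rejected.
#'
#' Keys (defaults in parentheses):
#' \describe{
#'   \item{registration}{`alpha` (0.35), `max_iter` (100), `tol` (1e-6 mm).}
#'   \item{interp}{`N` (48) points per resampled short-axis contour; `M`
#'     (NULL) output levels per group, NULL ties the inter-level spacing to
#'     the intra-contour point spacing.}
#'   \item{recon}{`h_mm` (NULL, defaults to the median delineated point
#'     spacing), `grid_expand_frac` (0.1), `max_tets` (2e6).}
#'   \item{post}{`smooth_iters` (10), `lambda` (0.5), `mu` (-0.53),
#'     `target_edge_mm` (NULL = grid spacing), `remesh` (TRUE).}
#' }
#'
#' @param ... named lists overriding sections, e.g.
#'   `registration = list(alpha = 0.3)`.
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    registration = list(alpha = 0.35, max_iter = 100, tol = 1e-6),
    interp = list(N = 48, M = NULL),
    recon = list(h_mm = NULL, grid_expand_frac = 0.1, max_tets = 2e6),
    post = list(smooth_iters = 10, lambda = 0.5, mu = -0.53,
                target_edge_mm = NULL, remesh = TRUE))
  user <- list(...)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop_lheart("lheart_parameter_error",
                sprintf("unknown config section(s): %s",
                        paste(bad, collapse = ", ")))
  for (sec in names(user)) {
    badk <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(badk) > 0)
      stop_lheart("lheart_parameter_error",
                  sprintf("unknown config key(s) in %s: %s", sec,
                          paste(badk, collapse = ", ")))
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  defaults
}

sax_contour_list <- function(study) {
  out <- list()
  for (ct in study$contours) {
    meta <- study$planes[[ct$plane_id]]
    if (meta$view != "sax") next
    out[[length(out) + 1]] <- list(points = project_contour_to_3d(ct, meta),
                                   label = ct$label)
  }
  out
}

# median spacing between consecutive delineated points (mm) across the
# short-axis contours: the scale the auxiliary grid defaults to
delineation_spacing <- function(sax_list) {
  d <- unlist(lapply(sax_list, function(ct) {
    p <- ct$points
    n <- nrow(p)
    sqrt(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
  }))
  median(d)
}

#' Reconstruct a left-heart surface from a contour study
#'
#' Runs the full chain: project contours into patient coordinates,
#' register the long-axis clouds to the short-axis stack (mutual-subset
#' filtering + ICP), densify the LV/LA/AO short-axis groups by PCHIP
#' interpolation (the bifurcation region is never interpolated), solve
#' the distance-weighted minimal-surface energy on a Delaunay tetrahedral
#' mesh by min-cut, extract and post-process the surface, and score it
#' against the long-axis reference contours.
#'
#' @param study a `contour_study`.
#' @param config a [pipeline_config()].
#' @param skip_registration logical; skip the rigid registration stage
#'   (the long-axis clouds are used as-is).
#' @param postprocess logical; apply Taubin smoothing and remeshing.
#' @param reference_study optional `contour_study` providing the
#'   validation reference planes/contours (defaults to `study`).
#' @param validate logical; compute the long-axis validation table.
#' @return list of class `lheart_reconstruction` with elements `surface`,
#'   `raw_surface`, `validation`, `registration`, `config`, `info`.
#' @export
reconstruct_study <- function(study, config = pipeline_config(),
                              skip_registration = FALSE, postprocess = TRUE,
                              reference_study = NULL, validate = TRUE) {
  stopifnot(inherits(study, "contour_study"))
  t0 <- proc.time()[["elapsed"]]

  cloud <- project_study(study)
  reg <- NULL
  if (!skip_registration && any(cloud$view != "sax")) {
    reg <- register_study(cloud, alpha = config$registration$alpha,
                          max_iter = config$registration$max_iter,
                          tol = config$registration$tol)
    cloud <- reg$cloud
  }

  sax_list <- sax_contour_list(study)
  if (length(sax_list) == 0)
    stop_lheart("lheart_parameter_error", "study has no short-axis contours")
  sax_meta <- Filter(function(p) p$view == "sax", study$planes)[[1]]
  normal <- plane_normal(sax_meta)
  dens <- densify_groups(sax_list, n = config$interp$N, m = config$interp$M,
                         normal = normal)
  lax_pts <- cloud$points[cloud$view != "sax", , drop = FALSE]
  c_new <- rbind(dens$points, lax_pts)

  h <- config$recon$h_mm
  if (is.null(h)) h <- delineation_spacing(sax_list)
  # merged bifurcation sections seed the cut but are never interpolated
  sax_levels <- sort(unique(round(vapply(sax_list, function(ct)
    mean(ct$points %*% normal), 0), 6)))
  slab <- if (length(sax_levels) > 1) median(diff(sax_levels)) / 2 else 4
  extra <- lapply(dens$merged, function(p)
    list(points = p, normal = normal, slab = slab))
  raw <- reconstruct_surface(c_new, dens$matrices, h = h,
                             expand = config$recon$grid_expand_frac,
                             cap = config$recon$max_tets / 6,
                             extra_polygons = extra)

  surf <- raw
  if (postprocess) {
    if (config$post$smooth_iters > 0)
      surf <- smooth_taubin(surf, iterations = config$post$smooth_iters,
                            lambda = config$post$lambda, mu = config$post$mu)
    if (isTRUE(config$post$remesh)) {
      te <- config$post$target_edge_mm
      if (is.null(te)) te <- h
      surf <- remesh_isotropic(surf, target_edge = te)
      surf <- smooth_taubin(surf, iterations = 2,
                            lambda = config$post$lambda, mu = config$post$mu)
    }
  }

  val <- NULL
  if (validate) {
    ref <- if (is.null(reference_study)) study else reference_study
    if (any(vapply(ref$planes, `[[`, "", "view") != "sax"))
      val <- validate_study(surf, ref)
  }

  structure(list(
    surface = surf, raw_surface = raw, validation = val,
    registration = if (is.null(reg)) NULL else
      reg[c("transforms", "diagnostics")],
    config = config,
    info = c(attr(raw, "recon_info"),
             list(n_lax = nrow(lax_pts),
                  elapsed_s = proc.time()[["elapsed"]] - t0))),
    class = "lheart_reconstruction")
}

#' @export
print.lheart_reconstruction <- function(x, ...) {
  cat(sprintf("<lheart_reconstruction: %d vertices, %d triangles (%.1f s)>\n",
              nrow(x$surface$vertices), nrow(x$surface$triangles),
              x$info$elapsed_s))
  if (!is.null(x$validation)) {
    m <- attr(x$validation, "means")
    cat(sprintf("  long-axis validation: H = %.2f mm, D = %.3f, J = %.3f\n",
                m["hausdorff_mm"], m["dice"], m["jaccard"]))
  }
  invisible(x)
}
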