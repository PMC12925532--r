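#' Sphericity of a solid from its volume and surface area
#'
#' IBSI definition `(36 pi V^2)^(1/3) / A`: 1 for a perfect sphere, smaller
#' for any other shape (the sphere minimizes area at fixed volume).
#'
#' @param V volume, mm^3 (> 0).
#' @param A surface area, mm^2 (> 0).
#' @return Sphericity in (0, 1] (up to numerical tolerance).
#' @examples
#' sphericity(4 / 3 * pi * 5^3, 4 * pi * 5^2)  # 1
#' sphericity(1, 6)                             # unit cube, ~0.806
#' @export
sphericity <- function(V, A) {
  if (any(!is.finite(V)) || any(V <= 0)) stop("`V` must be positive")
  if (any(!is.finite(A)) || any(A <= 0)) stop("`A` must be positive")
  (36 * pi * V^2)^(1 / 3) / A
}

#' Principal axes, elongation and flatness of a voxel mask
#'
#' Eigen-decomposition of the (population) covariance of the foreground
#' voxel-center coordinates in mm. Following the IBSI convention, axis
#' lengths are `2 * sqrt(5 * lambda)` (exact for a uniform solid ellipsoid),
#' elongation is `sqrt(lambda2 / lambda1)` (minor/major axis-length ratio)
#' and flatness is `sqrt(lambda3 / lambda1)` (least/major).
#'
#' @param mask a [voxel_mask()] with at least 4 non-collinear foreground voxels.
#' @return List with `axis_lengths` (mm, descending), `eigenvalues`,
#'   `elongation`, `flatness`, `center` (mm centroid).
#' @export
principal_axes <- function(mask) {
  xyz <- mask_coordinates(mask)
  if (nrow(xyz) < 4L) stop("need at least 4 foreground voxels")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  cv <- crossprod(xc) / nrow(xc)
  ev <- eigen(cv, symmetric = TRUE)$values        # descending
  if (ev[1] <= 0 || ev[3] / ev[1] < 1e-10)
    stop("degenerate voxel cloud (collinear or coplanar): mask too thin")
  list(axis_lengths = 2 * sqrt(5 * ev),
       eigenvalues = ev,
       elongation = sqrt(ev[2] / ev[1]),
       flatness = sqrt(ev[3] / ev[1]),
       center = ctr)
}

#' Per-vertex principal curvatures of a surface mesh
#'
#' At each vertex a quadric height field is fitted by least squares over the
#' neighbourhood of vertices reachable along edges within Euclidean distance
#' `radius`, expressed in the tangent frame of the (outward) vertex normal;
#' the principal curvatures are the eigenvalues of the resulting Monge-patch
#' shape operator. Convex regions of an outward-oriented surface get
#' positive curvatures. Vertices with too few neighbours (isolated or near-
#' degenerate) are flagged invalid.
#'
#' The neighbourhood radius trades noise robustness against locality; on
#' marching-tetrahedra meshes of anti-aliased masks, about 12 voxel widths
#' recovers analytic curvatures of spheres and cylinders to a few percent.
#'
#' On meshes with more than `max_vertices` vertices, curvature is evaluated
#' at a deterministic, evenly spaced vertex subsample (the rest are flagged
#' invalid); aggregate statistics such as medians are unaffected while the
#' quadratic neighbourhood cost stays bounded.
#'
#' @param mesh a [surface_mesh()] (watertight, outward-oriented).
#' @param radius neighbourhood radius in mm. Default: 25 x mean edge length.
#' @param max_vertices evaluation budget (default 20000).
#' @return A data.frame with columns `k1`, `k2` (mm^-1, `k1 >= k2`) and
#'   `valid`; attributes `radius` and `n_evaluated`.
#' @export
principal_curvatures <- function(mesh, radius = NULL, max_vertices = 20000L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(radius)) {
    e <- mesh_edges(mesh)
    len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    radius <- 25 * mean(len)
  }
  nv <- nrow(mesh$vertices)
  targets <- if (nv > max_vertices)
    unique(as.integer(round(seq(1, nv, length.out = max_vertices)))) - 1L
  else seq_len(nv) - 1L
  nrm <- vertex_normals(mesh)
  res <- cpp_curvatures(mesh$vertices, mesh$faces, nrm, radius, targets)
  out <- data.frame(k1 = res$k1, k2 = res$k2, valid = res$valid)
  out$k1[!out$valid] <- NA_real_
  out$k2[!out$valid] <- NA_real_
  attr(out, "radius") <- radius
  attr(out, "n_evaluated") <- length(targets)
  out
}

#' Koenderink shape index from principal curvatures
#'
#' `S = (2/pi) * atan((k1 + k2) / (k1 - k2))` on `[-1, 1]`: -1 concave
#' umbilic (cup), 0 symmetric saddle, +1 convex umbilic (cap). Umbilic
#' points (`k1 == k2`) map to +1 or -1 by the sign of the mean curvature;
#' planar points (`k1 == k2 == 0`) are undefined and return `NA`.
#'
#' @param k1,k2 principal curvatures, mm^-1 (`k1 >= k2`), vectorized.
#' @return Shape index values in `[-1, 1]`, `NA` for planar points.
#' @export
shape_index <- function(k1, k2) {
  s <- (2 / pi) * atan2(k1 + k2, k1 - k2)
  s[abs(k1) < 1e-12 & abs(k2) < 1e-12] <- NA_real_
  pmin(1, pmax(-1, s))
}

#' Koenderink curvedness from principal curvatures
#'
#' `C = sqrt((k1^2 + k2^2) / 2)`, mm^-1: 0 only for planar points, large for
#' strongly curved surface (scale companion of the shape index).
#'
#' @param k1,k2 principal curvatures, mm^-1, vectorized.
#' @export
curvedness <- function(k1, k2) sqrt((k1^2 + k2^2) / 2)

#' Quantify the seven morphology parameters of one aneurysm
#'
#' Runs the full single-aneurysm morphometry: iso-surface mesh (unless one is
#' supplied), volume and surface area from the mesh, sphericity, principal-
#' axis elongation and flatness from the voxel cloud, and per-vertex shape
#' index / curvedness summarized by their median over valid vertices.
#' Display copies of sphericity, elongation, flatness, shape index and
#' curvedness are scaled by 100 for readability, matching the reporting
#' convention used for cohort tables.
#'
#' @param mask a [voxel_mask()] (single 26-connected component).
#' @param mesh optional precomputed [surface_mesh()] for `mask`.
#' @param curvature_radius neighbourhood radius (mm) for
#'   [principal_curvatures()]; default 12 x mean voxel spacing.
#' @param smooth_sigma passed to [extract_mesh()].
#' @param min_valid_vertices below this number of valid curvature vertices
#'   the local-shape medians are flagged unreliable (warning).
#' @return An object of class `morphology_record`: list with `volume`,
#'   `surface_area`, `sphericity`, `elongation`, `flatness`,
#'   `median_shape_index`, `median_curvedness`, `axis_lengths`,
#'   `n_valid_vertices`, and `display` (the x100 copies).
#' @export
summarize_morphology <- function(mask, mesh = NULL, curvature_radius = NULL,
                                 smooth_sigma = 1, min_valid_vertices = 50L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (is.null(mesh)) mesh <- extract_mesh(mask, smooth_sigma = smooth_sigma)
  if (is.null(curvature_radius)) curvature_radius <- 12 * mean(mask$spacing)
  V <- mesh_volume(mesh)
  A <- mesh_surface_area(mesh)
  ax <- principal_axes(mask)
  cf <- principal_curvatures(mesh, radius = curvature_radius)
  s <- shape_index(cf$k1, cf$k2)
  cv <- curvedness(cf$k1, cf$k2)
  ok <- cf$valid & !is.na(s)
  if (sum(ok) < min_valid_vertices)
    warning("only ", sum(ok), " valid curvature vertices: local shape medians unreliable")
  rec <- list(volume = V,
              surface_area = A,
              sphericity = sphericity(V, A),
              elongation = ax$elongation,
              flatness = ax$flatness,
              median_shape_index = stats::median(s[ok]),
              median_curvedness = stats::median(cv[ok]),
              axis_lengths = ax$axis_lengths,
              n_valid_vertices = sum(ok),
              curvature_radius = curvature_radius)
  rec$display <- list(sphericity = 100 * rec$sphericity,
                      elongation = 100 * rec$elongation,
                      flatness = 100 * rec$flatness,
                      median_shape_index = 100 * rec$median_shape_index,
                      median_curvedness = 100 * rec$median_curvedness)
  class(rec) <- "morphology_record"
  rec
}

#' @export
print.morphology_record <- function(x, ...) {
  cat(sprintf(paste0("<morphology_record> V=%.2f mm^3, A=%.2f mm^2, sphericity=%.3f,\n",
                     "  elongation=%.3f, flatness=%.3f, median S=%.3f, median C=%.4f mm^-1\n"),
              x$volume, x$surface_area, x$sphericity, x$elongation, x$flatness,
              x$median_shape_index, x$median_curvedness))
  invisible(x)
}

#' One-row data.frame for a morphology record (raw + x100 display columns)
#' @param x a `morphology_record`.
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused).
#' @export
as.data.frame.morphology_record <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(volume_mm3 = x$volume,
             surface_area_mm2 = x$surface_area,
             sphericity = x$sphericity,
             elongation = x$elongation,
             flatness = x$flatness,
             median_shape_index = x$median_shape_index,
             median_curvedness = x$median_curvedness,
             sphericity_x100 = x$display$sphericity,
             elongation_x100 = x$display$elongation,
             flatness_x100 = x$display$flatness,
             shape_index_x100 = x$display$median_shape_index,
             curvedness_x100 = x$display$median_curvedness,
             n_valid_vertices = x$n_valid_vertices)
}

#' Write morphology records to CSV (one row per aneurysm)
#' @param records a named list of `morphology_record`s (names become the `id` column).
#' @param path output CSV path.
#' @export
write_morphology_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, as.data.frame))
  rows <- cbind(id = if (is.null(names(records))) seq_along(records) else names(records), rows)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
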