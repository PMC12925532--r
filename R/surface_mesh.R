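#' Triangle surface mesh in mm coordinates
#'
#' @param vertices n x 3 numeric matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices; triangles are
#'   wound counter-clockwise seen from outside (outward normals).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, Euler characteristic %d\n",
              nrow(x$vertices), nrow(x$faces), mesh_euler(x)))
  invisible(x)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE], f[, c(3, 1), drop = FALSE])
}

#' Euler characteristic V - E + F (2 for a closed genus-0 surface)
#' @param mesh a [surface_mesh()].
#' @export
mesh_euler <- function(mesh) {
  e <- mesh_edges(mesh)
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

#' Is the mesh a closed, consistently oriented 2-manifold?
#'
#' Checks that every undirected edge is shared by exactly two faces and that
#' the two incident faces traverse it in opposite directions.
#' @param mesh a [surface_mesh()].
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  if (nrow(e) == 0) return(FALSE)
  key_dir <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key_dir)) return(FALSE)          # inconsistent winding / non-manifold
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key_und) == 2L)
}

#' Enclosed volume of a watertight mesh (divergence theorem), mm^3
#'
#' Sum of signed tetrahedron volumes against the origin; positive under the
#' outward-orientation convention.
#' @param mesh a [surface_mesh()].
#' @param check verify watertightness first (default TRUE).
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (check && !is_watertight(mesh))
    stop("mesh is not watertight; volume is undefined")
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Total surface area of a mesh, mm^2
#'
#' Degenerate (zero-area) triangles contribute 0; their count is reported via
#' a message when `quiet = FALSE`.
#' @param mesh a [surface_mesh()].
#' @param quiet suppress the degenerate-triangle message.
#' @export
mesh_surface_area <- function(mesh, quiet = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  e1 <- v[mesh$faces[, 2], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  e2 <- v[mesh$faces[, 3], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  ndeg <- sum(areas == 0)
  if (ndeg > 0 && !quiet)
    message(ndeg, " degenerate triangle(s) contributed zero area")
  sum(areas)
}

#' Outward unit vertex normals (area-weighted face-normal average)
#' @param mesh a [surface_mesh()].
#' @export
vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  cpp_vertex_normals(mesh$vertices, mesh$faces)
}

#' Extract a watertight iso-surface mesh from a binary mask
#'
#' The occupancy field is anti-aliased with a small Gaussian filter
#' (`smooth_sigma`, in voxel units) and iso-surfaced with a marching-
#' tetrahedra scan (6-tetrahedra cell decomposition with consistent face
#' diagonals, linear edge interpolation) at the given level. The mask is
#' always padded with background so the surface closes even when foreground
#' touches the grid boundary. Output coordinates are mm (spacing and origin
#' applied); winding is outward (positive signed volume).
#'
#' Anti-aliasing matters: iso-surfacing a raw binary field yields a surface
#' whose *area* does not converge to the true area (approximately +9% for a
#' sphere), while `sigma = 1` voxel brings both volume and area within a
#' fraction of a percent at `radius / spacing >= 20`. The filter slightly
#' rounds sharp edges (a voxelized cube loses about 1% of area per 0.2
#' voxels of sigma, vanishing as the voxels shrink); since aneurysm
#' segmentations are smooth blobs, accuracy on curved surfaces wins and the
#' default is 1 voxel. Set `smooth_sigma = 0` for the raw behaviour. No
#' mesh-vertex smoothing is performed.
#'
#' @param mask a [voxel_mask()]; should be a single connected component.
#' @param level iso level in (0, 1), default 0.5.
#' @param smooth_sigma Gaussian sigma in voxels applied to the occupancy field
#'   before surfacing (default 1; 0 disables).
#' @return A [surface_mesh()].
#' @export
extract_mesh <- function(mask, level = 0.5, smooth_sigma = 1) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  pad <- as.integer(ceiling(4 * max(smooth_sigma, 0)) + 2L)
  m <- pad_mask(mask, pad)
  field <- array(as.double(m$values), dim(m$values))
  if (smooth_sigma > 0)
    field <- cpp_gaussian_smooth(field, rep(smooth_sigma, 3))
  res <- cpp_march_tets(field, level, m$spacing, m$origin)
  mesh <- surface_mesh(res$vertices, res$faces)
  if (nrow(mesh$faces) == 0L)
    stop("empty iso-surface: level outside field range?")
  if (mesh_volume(mesh, check = FALSE) < 0)   # defensive; winding is outward by construction
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  if (!is_watertight(mesh))
    stop("iso-surface is not watertight (unexpected after padding)")
  mesh
}
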