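#' Binary segmentation mask on a regular voxel grid
#'
#' A `voxel_mask` couples a binary 3D array (foreground = aneurysm) with its
#' physical voxel spacing in mm and the world-coordinate offset of the grid.
#' World coordinates follow the voxel-center convention
#' `world = origin + index * spacing` with 0-based indices.
#'
#' @param values 3D array (logical or numeric, coerced to 0/1 integer).
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, mm offset of voxel (0,0,0).
#' @return An object of class `voxel_mask`.
#' @examples
#' a <- array(0L, c(5, 5, 5)); a[2:4, 2:4, 2:4] <- 1L
#' m <- voxel_mask(a, spacing = c(1, 1, 1))
#' mask_volume(m)  # 27 voxels x 1 mm^3
#' @export
voxel_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  v <- array(as.integer(values != 0), dim(values))
  if (!any(v == 1L)) stop("mask has no foreground voxels")
  structure(list(values = v, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels @ (%s) mm, %d foreground (%.2f mm^3)\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", "),
              sum(x$values), mask_volume(x)))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$values)

#' Voxel-counting volume of a mask (foreground count x voxel volume, mm^3)
#' @param mask a [voxel_mask()].
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$values) * prod(mask$spacing)
}

#' World-coordinates (mm) of all foreground voxel centers
#' @param mask a [voxel_mask()].
#' @return n x 3 matrix of mm coordinates.
#' @export
mask_coordinates <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  idx <- which(mask$values == 1L, arr.ind = TRUE) - 1L  # 0-based
  sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Pad a mask with background voxels on every side
#'
#' The origin is shifted so world coordinates of existing voxels are unchanged.
#' @param mask a [voxel_mask()].
#' @param n number of background layers to add on each face.
#' @export
pad_mask <- function(mask, n = 1L) {
  stopifnot(inherits(mask, "voxel_mask"), n >= 0)
  if (n == 0) return(mask)
  d <- dim(mask$values)
  out <- array(0L, d + 2L * n)
  out[(n + 1):(n + d[1]), (n + 1):(n + d[2]), (n + 1):(n + d[3])] <- mask$values
  voxel_mask(out, mask$spacing, mask$origin - n * mask$spacing)
}

#' Resample a mask to a new voxel spacing
#'
#' Harmonizes heterogeneous acquisitions onto a common grid: the binary field
#' is interpolated trilinearly and re-thresholded at 0.5. The output grid
#' covers the same physical extent (dimensions `ceiling(dim * spacing /
#' target)`), shares the input origin, and uses the voxel-center convention.
#'
#' @param mask a [voxel_mask()].
#' @param target_spacing new spacing, mm (scalar or length 3); default 0.25 mm
#'   isotropic, finer than typical CTA/TOF-MRA voxels so that downstream shape
#'   features are resolution-stable.
#' @return A [voxel_mask()] at the new spacing.
#' @export
resample_mask <- function(mask, target_spacing = 0.25) {
  stopifnot(inherits(mask, "voxel_mask"))
  ts <- as.numeric(target_spacing)
  if (length(ts) == 1L) ts <- rep(ts, 3L)
  if (any(!is.finite(ts)) || any(ts <= 0)) stop("`target_spacing` must be positive")
  d <- dim(mask$values)
  out_dim <- pmax(1L, as.integer(ceiling(d * mask$spacing / ts - 1e-6)))
  field <- cpp_trilinear_resample(array(as.double(mask$values), d),
                                  mask$spacing, out_dim, ts)
  vals <- field >= 0.5
  if (!any(vals))
    stop("no foreground after resampling: target spacing too coarse for this mask")
  # cell-aligned grids: output voxel centers shift by half the spacing change
  voxel_mask(array(vals, out_dim), ts, mask$origin + (ts - mask$spacing) / 2)
}

#' Keep only the largest 26-connected foreground component
#'
#' Guards the single-aneurysm assumption of the morphometry pipeline. If two
#' components tie in voxel count, the one whose seed voxel has the lowest
#' linear (column-major) index is kept.
#'
#' @param mask a [voxel_mask()].
#' @return A [voxel_mask()] with a single connected component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  lab <- cpp_label_components(mask$values)
  counts <- tabulate(lab[lab > 0L])
  if (length(counts) <= 1L) return(mask)
  keep <- which.max(counts)  # ties -> smallest label = earliest seed voxel
  voxel_mask(array(lab == keep, dim(mask$values)), mask$spacing, mask$origin)
}

#' Number of 26-connected foreground components
#' @param mask a [voxel_mask()].
#' @export
n_components <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  max(cpp_label_components(mask$values))
}
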