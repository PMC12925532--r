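# Fixtures built in code: hand-made meshes and small masks.

# unit cube [0,1]^3 as 12 outward-wound triangles
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left
             c(2, 3, 7), c(2, 7, 6))   # right
  surface_mesh(v, f)
}

# voxel ball: foreground where |x - c| <= r (units: voxels), spacing in mm
ball_mask <- function(r_vox, spacing = 1, margin = 3L, center_off = c(0, 0, 0)) {
  n <- as.integer(2 * ceiling(r_vox) + 2 * margin + 1)
  ctr <- (n - 1) / 2 + center_off
  x2 <- (seq_len(n) - 1 - ctr[1])^2
  y2 <- (seq_len(n) - 1 - ctr[2])^2
  z2 <- (seq_len(n) - 1 - ctr[3])^2
  d2 <- outer(outer(x2, y2, "+"), z2, "+")
  voxel_mask(d2 <= r_vox^2, spacing)
}

# two balls of different radii in one grid
two_ball_mask <- function(r1 = 5, r2 = 3, spacing = 1) {
  n <- 2L * (r1 + r2) + 16L
  a <- array(FALSE, c(n, n, n))
  mk <- function(ctr, r) {
    x2 <- (seq_len(n) - 1 - ctr[1])^2
    y2 <- (seq_len(n) - 1 - ctr[2])^2
    z2 <- (seq_len(n) - 1 - ctr[3])^2
    outer(outer(x2, y2, "+"), z2, "+") <= r^2
  }
  a <- mk(c(r1 + 3, r1 + 3, r1 + 3), r1) | mk(c(n - r2 - 4, n - r2 - 4, n - r2 - 4), r2)
  voxel_mask(a, spacing)
}

seven_params <- function(rec) {
  c(volume = rec$volume, area = rec$surface_area, sphericity = rec$sphericity,
    elongation = rec$elongation, flatness = rec$flatness,
    shape_index = rec$median_shape_index, curvedness = rec$median_curvedness)
}

# small, fast simulation parameters
fast_params <- function(...) sim_params(n = 326L, ...)
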