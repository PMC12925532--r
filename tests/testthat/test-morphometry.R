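# Shape parameters: closed-form oracles and invariances.

test_that("sphericity closed forms and monotonicity", {
  r <- 5
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1.0)
  expect_equal(sphericity(1, 6), (36 * pi)^(1 / 3) / 6)  # unit cube, ~0.80600
  A <- seq(5, 20, by = 0.5)
  expect_true(all(diff(sphericity(1, A)) < 0))           # fixed V, growing A
  expect_error(sphericity(-1, 6), "positive")
  expect_error(sphericity(1, 0), "positive")
})

test_that("principal_axes recovers ellipsoid axis ratios and is rotation invariant", {
  # voxelized ball is isotropic
  ax <- principal_axes(ball_mask(8))
  expect_lt(abs(ax$elongation - 1), 0.02)
  expect_lt(abs(ax$flatness - 1), 0.02)
  expect_true(all(diff(ax$axis_lengths) <= 0))
  # solid ellipsoid (4,2,1)mm: elongation 0.50, flatness 0.25
  pe <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(4, 2, 1), spacing = 0.15))
  ax <- principal_axes(pe$mask)
  expect_lt(abs(ax$elongation - 0.50), 0.01)
  expect_lt(abs(ax$flatness - 0.25), 0.01)
  expect_lt(abs(ax$axis_lengths[1] - 8) / 8, 0.02)
  # rotation invariance
  per <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(4, 2, 1), spacing = 0.15,
                                   rotation = c(25, 40, 65)))
  axr <- principal_axes(per$mask)
  expect_lt(abs(axr$elongation - ax$elongation) / ax$elongation, 0.02)
  expect_lt(abs(axr$flatness - ax$flatness) / ax$flatness, 0.02)
  # degenerate cloud rejected
  flat <- array(0L, c(6, 6, 3)); flat[2:5, 2:5, 2] <- 1L
  expect_error(principal_axes(voxel_mask(flat, 1)), "degenerate|thin")
})

test_that("shape_index: conventions, closed forms, range", {
  expect_equal(shape_index(0.1, 0.1), 1)         # convex umbilic
  expect_equal(shape_index(-0.1, -0.1), -1)      # concave umbilic
  expect_equal(shape_index(0.1, -0.1), 0)        # symmetric saddle
  expect_equal(shape_index(0.2, 0), 0.5)         # ridge: (2/pi) atan(1)
  expect_true(is.na(shape_index(0, 0)))          # planar -> invalid
  # property: S in [-1,1] for any ordered pair
  set.seed(42)
  k1 <- rnorm(500); k2 <- rnorm(500)
  hi <- pmax(k1, k2); lo <- pmin(k1, k2)
  s <- shape_index(hi, lo)
  expect_true(all(is.na(s) | (s >= -1 & s <= 1)))
})

test_that("curvedness: closed forms and non-negativity", {
  expect_equal(curvedness(1 / 7, 1 / 7), 1 / 7)      # sphere r=7
  expect_equal(curvedness(0, 0), 0)                  # plane
  expect_equal(curvedness(3, 4), sqrt(12.5))
  set.seed(7)
  expect_true(all(curvedness(rnorm(200), rnorm(200)) >= 0))
})

test_that("principal_curvatures matches analytic surfaces", {
  # sphere r=10: k1 ~ k2 ~ 0.1
  # moderate resolution (r/h = 25): k1 carries a small positive noise-selection
  # bias; the 5% fine-mesh check runs at 0.25 mm in the acceptance suite
  mesh <- extract_mesh(ball_mask(25, spacing = 0.4))
  cf <- principal_curvatures(mesh, radius = 12 * 0.4)
  expect_lt(abs(median(cf$k1, na.rm = TRUE) - 0.1) / 0.1, 0.10)
  expect_lt(abs(median(cf$k2, na.rm = TRUE) - 0.1) / 0.1, 0.08)
  expect_true(all(cf$k1 >= cf$k2, na.rm = TRUE))
  # cylinder side (capsule r=5, away from the caps): k1 ~ 0.2, k2 ~ 0
  pc <- make_phantom(phantom_spec("capsule", radius = 5, length = 10, spacing = 0.3))
  cmesh <- extract_mesh(pc$mask)
  ccf <- principal_curvatures(cmesh, radius = 12 * 0.3)
  mid <- abs(cmesh$vertices[, 3]) < 2.5 & ccf$valid
  expect_lt(abs(median(ccf$k1[mid]) - 0.2) / 0.2, 0.15)
  expect_lt(abs(median(ccf$k2[mid])), 0.03)
})

test_that("curvature medians converge to closed forms with refinement", {
  errs <- sapply(c(0.8, 0.4, 0.2), function(sp) {
    ph <- make_phantom(phantom_spec("sphere", radius = 6, spacing = sp))
    r <- suppressWarnings(summarize_morphology(ph$mask))
    c(V = abs(r$volume - ph$truth$volume) / ph$truth$volume,
      A = abs(r$surface_area - ph$truth$surface_area) / ph$truth$surface_area,
      S = abs(r$median_shape_index - 1),
      C = abs(r$median_curvedness - 1 / 6) * 6)
  })
  expect_true(all(diff(errs["V", ]) < 0))
  expect_true(all(diff(errs["A", ]) < 0))
  expect_true(all(diff(errs["C", ]) < 0))
  expect_lt(errs["S", 3], errs["S", 1])
  expect_lt(errs["S", 3], 0.02)
  expect_lt(errs["C", 3], 0.05)
})

test_that("summarize_morphology: sphere oracle, ellipsoid, bleb effect, display x100", {
  rec <- summarize_morphology(ball_mask(25, spacing = 0.4))
  expect_gt(rec$sphericity, 0.99)
  expect_lt(abs(rec$median_shape_index - 1), 0.02)
  expect_lt(abs(rec$median_curvedness - 0.1) / 0.1, 0.08)  # coarse regime
  expect_equal(rec$display$sphericity, 100 * rec$sphericity)
  expect_equal(rec$display$median_curvedness, 100 * rec$median_curvedness)
  # ellipsoid: lower sphericity than sphere, elongation ~ 0.5
  pe <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(8, 4, 2), spacing = 0.4))
  re <- summarize_morphology(pe$mask)
  expect_lt(re$sphericity, rec$sphericity)
  expect_lt(abs(re$elongation - 0.5), 0.02)
  # blebs strictly lower sphericity and raise area vs the bare sphere
  pb <- make_phantom(phantom_spec("sphere_with_blebs", radius = 6, n_blebs = 2,
                                  bleb_frac = 0.4, spacing = 0.4, seed = 3))
  ps <- make_phantom(phantom_spec("sphere", radius = 6, spacing = 0.4))
  rb <- summarize_morphology(pb$mask); rs <- summarize_morphology(ps$mask)
  expect_lt(rb$sphericity, rs$sphericity)
  expect_gt(rb$surface_area, rs$surface_area)
  # few valid vertices -> warning
  tiny <- ball_mask(3, spacing = 1)
  expect_warning(summarize_morphology(tiny, min_valid_vertices = 1e6), "unreliable")
})

test_that("scale law: spacing scaling leaves dimensionless parameters, divides C by s", {
  ph <- make_phantom(phantom_spec("sphere_with_blebs", radius = 6, n_blebs = 2,
                                  bleb_frac = 0.4, spacing = 0.4, seed = 3))
  s <- 1.8
  scaled <- voxel_mask(ph$mask$values, ph$mask$spacing * s, ph$mask$origin * s)
  r1 <- summarize_morphology(ph$mask)
  r2 <- summarize_morphology(scaled)
  expect_lt(abs(r2$sphericity - r1$sphericity) / r1$sphericity, 0.01)
  expect_lt(abs(r2$elongation - r1$elongation) / r1$elongation, 0.01)
  expect_lt(abs(r2$flatness - r1$flatness) / r1$flatness, 0.01)
  expect_lt(abs(r2$median_shape_index - r1$median_shape_index), 0.01)
  expect_lt(abs(r2$median_curvedness - r1$median_curvedness / s) /
              (r1$median_curvedness / s), 0.02)
  expect_lt(abs(r2$volume - r1$volume * s^3) / (r1$volume * s^3), 1e-9)
})

test_that("morphology CSV writer produces stable columns", {
  rec <- suppressWarnings(summarize_morphology(ball_mask(5)))
  path <- tempfile(fileext = ".csv")
  write_morphology_csv(list(a = rec, b = rec), path)
  df <- read.csv(path)
  expect_equal(nrow(df), 2L)
  expect_true(all(c("id", "volume_mm3", "surface_area_mm2", "sphericity",
                    "elongation", "flatness", "median_shape_index",
                    "median_curvedness", "sphericity_x100", "shape_index_x100",
                    "curvedness_x100") %in% names(df)))
  expect_equal(df$sphericity_x100, 100 * df$sphericity)
})
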