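# Segmentation, cropping, volume, surface area, convex hull and porosity,
# checked against analytic phantoms and exhaustive brute-force oracles.

cuboid_phantom <- function(noise_sd = 0, seed = 1L, grid = 14) {
  generate_voxel_phantom(
    phantom_spec("cuboid", grid_dims = grid, voxel_spacing = 100,
                 edge_um = 1000, rng_seed = seed),
    noise_sd = noise_sd)
}

sphere_phantom <- function(r_vox = 30, spacing = 100, margin = 6, seed = 1L, ...) {
  generate_voxel_phantom(
    phantom_spec("sphere", grid_dims = 2 * r_vox + 2 * margin,
                 voxel_spacing = spacing, radius_um = spacing * r_vox,
                 rng_seed = seed), ...)
}

test_that("Otsu segmentation recovers a clean bimodal phantom exactly", {
  ph <- cuboid_phantom()
  m <- segment(ph$grid)
  expect_identical(m$mask, ph$truth$mask)
  expect_true(m$threshold > 30 && m$threshold < 200)
  expect_identical(m$components_removed, 0L)
})

test_that("speckles below the minimum component size are removed and counted", {
  ph <- cuboid_phantom()
  g <- ph$grid
  g$intensities[1, 1, 1:5] <- 200  # a 5-voxel speckle far from the cuboid
  m <- segment(g)
  expect_identical(m$mask, ph$truth$mask)
  expect_identical(m$components_removed, 1L)
  # the speckle survives if the cleanup floor is lowered
  m2 <- segment(g, min_component_size = 2L)
  expect_identical(sum(m2$mask), sum(ph$truth$mask) + 5L)
})

test_that("segmentation of a noisy phantom overlaps the generative mask (Dice >= 0.99)", {
  ph <- sphere_phantom(r_vox = 15, margin = 5, noise_sd = 20, seed = 3L)
  m <- segment(ph$grid)
  inter <- sum(m$mask & ph$truth$mask)
  dice <- 2 * inter / (sum(m$mask) + sum(ph$truth$mask))
  expect_gte(dice, 0.99)
})

test_that("empty-foreground segmentation errors name the threshold", {
  g <- voxel_grid(array(c(rep(0, 999), 1000), dim = c(10, 10, 10)), 100)
  # the single bright voxel is removed as a small component
  expect_error(segment(g), "empty foreground after thresholding at")
})

test_that("apex cropping keeps a proportional slab of a uniform stem", {
  # 70 mm stem along z at 1 mm spacing; crop to 40 mm -> 4/7 of the voxels
  mask <- array(FALSE, dim = c(80, 9, 9))
  mask[6:75, 4:6, 4:6] <- TRUE
  sm <- segmentation_mask(mask, spacing = 1000)
  cropped <- crop_top(sm, height_mm = 40)
  expect_equal(sum(cropped$mask) / sum(mask), 4 / 7)
  expect_identical(cropped$apex_slice, 6L)
  expect_equal(cropped$crop_height_mm, 40)
  # crop height beyond the object leaves the mask unchanged
  same <- crop_top(sm, height_mm = 75)
  expect_identical(same$mask, mask)
  # crop height beyond the grid warns and retains everything
  expect_warning(full <- crop_top(sm, height_mm = 200), "retaining full grid")
  expect_identical(full$mask, mask)
})

test_that("the apex is the first slice holding any foreground", {
  mask <- array(FALSE, dim = c(12, 6, 6))
  mask[5, , ] <- TRUE
  sm <- crop_top(segmentation_mask(mask, 500), height_mm = 2)
  expect_identical(sm$apex_slice, 5L)
})

test_that("plant volume counts voxels and is axis-permutation invariant", {
  ph <- cuboid_phantom()
  m <- segment(ph$grid)
  expect_equal(plant_volume(m), 1.0)
  # anisotropic permutation check on a random blob
  blob <- random_blob_mask(c(20, 24, 28), seed = 4)
  sp <- c(50, 80, 110)
  v0 <- plant_volume(segmentation_mask(blob, sp))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    v <- plant_volume(segmentation_mask(aperm(blob, perm), sp[perm]))
    expect_equal(v, v0, tolerance = 1e-12)
  }
})

test_that("face-count surface area is exact for cuboids and single voxels", {
  ph <- cuboid_phantom()
  expect_equal(surface_area(segment(ph$grid)), 6.0)  # 600 faces x 0.01 mm^2
  single <- array(FALSE, dim = c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(surface_area(segmentation_mask(single, 100)), 6 * 0.01)
  # anisotropic voxels weight each face orientation by its physical area
  slab <- array(TRUE, dim = c(1, 2, 2))
  sp <- c(10, 20, 40)
  expect_equal(surface_area(segmentation_mask(slab, sp)),
               (2 * (20 * 40) * 2 * 2 + 2 * (10 * 40) * 2 + 2 * (10 * 20) * 2) * 1e-6)
})

test_that("face counting matches the exhaustive 6-neighbour scan", {
  for (s in 1:3) {
    blob <- random_blob_mask(c(16, 18, 20), n_balls = 3, seed = s)
    sp <- c(100, 100, 100)
    fast <- surface_area(segmentation_mask(blob, sp))
    counts <- oracle_exposed_faces(blob)
    expect_equal(fast, sum(counts) * 0.01, tolerance = 1e-12)
  }
})

test_that("sphere area: face counting carries the 1.5 voxelization factor, the isosurface estimator does not", {
  ph <- sphere_phantom(r_vox = 30)
  m <- segment(ph$grid)
  truth <- ph$truth$analytic_surface_area_mm2
  expect_gt(surface_area(m, "face_count") / truth, 1.45)
  expect_lt(surface_area(m, "face_count") / truth, 1.55)
  expect_lt(abs(surface_area(m, "isosurface") / truth - 1), 0.03)
})

test_that("hulls of convex phantoms hug the foreground", {
  ph <- cuboid_phantom()
  m <- segment(ph$grid)
  h <- convex_hull(m)
  # hull over voxel centres: one half-voxel shell smaller than the solid
  expect_equal(h$hull_volume_mm3, 0.9^3, tolerance = 1e-9)
  expect_identical(sum(h$raster), sum(m$mask))  # rasterized hull == cuboid
  r <- porosity(m, h)
  expect_equal(r$porosity, 0)
  expect_equal(r$pore_volume_mm3, 0)
})

test_that("sphere hull volume approaches the closed form within 2%", {
  ph <- sphere_phantom(r_vox = 30)
  m <- segment(ph$grid)
  h <- convex_hull(m)
  expect_lt(abs(h$hull_volume_mm3 / ph$truth$analytic_hull_volume_mm3 - 1), 0.02)
  res <- porosity(m, h)
  expect_lte(res$porosity, 0.02)
})

test_that("two separated cuboids produce a hull spanning the gap", {
  mask <- array(FALSE, dim = c(10, 10, 30))
  mask[3:8, 3:8, 2:7] <- TRUE
  mask[3:8, 3:8, 24:29] <- TRUE
  m <- segmentation_mask(mask, 100)
  h <- convex_hull(m)
  expect_gt(h$hull_volume_mm3, 2 * plant_volume(m) / 2)  # > sum of parts
  # gap voxels between the cuboids are inside the hull
  expect_true(all(h$raster[3:8, 3:8, 8:23]))
  res <- porosity(m, h)
  expect_gt(res$porosity, 0.4)
  expect_equal(res$pore_volume_mm3, res$porosity * res$hull_volume_mm3,
               tolerance = 1e-12)
})

test_that("degenerate foreground is rejected with a 2D-fallback message", {
  flat <- array(FALSE, dim = c(6, 6, 6))
  flat[3, , ] <- TRUE  # a single plane of voxels
  expect_error(convex_hull(segmentation_mask(flat, 100)), "coplanar")
  line <- array(FALSE, dim = c(6, 6, 6))
  line[, 3, 3] <- TRUE
  expect_error(convex_hull(segmentation_mask(line, 100)), "collinear")
})

test_that("four corner stems give a porosity computable by hand counting", {
  # thin 1-voxel stems at the corners of a 11x11 voxel square, 8 slices
  mask <- array(FALSE, dim = c(8, 13, 13))
  for (yx in list(c(2, 2), c(2, 12), c(12, 2), c(12, 12))) {
    mask[1:8, yx[1], yx[2]] <- TRUE
  }
  m <- segmentation_mask(mask, 100)
  h <- convex_hull(m)
  # hull of the centres is the full 8 x 11 x 11 voxel prism
  expect_identical(sum(h$raster), 8L * 11L * 11L)
  res <- porosity(m, h)
  n_hull <- 8 * 11 * 11; n_fg <- 4 * 8
  expect_equal(res$porosity, (n_hull - n_fg) / n_hull)
  expect_equal(res$pore_volume_mm3, (n_hull - n_fg) * 1e-3)
})

test_that("volume and porosity are invariant under 90-degree z-rotations", {
  blob <- random_blob_mask(c(12, 20, 20), n_balls = 3, seed = 9)
  rot90 <- function(m) {
    d <- dim(m)
    aperm(m, c(1, 3, 2))[, d[3]:1, , drop = FALSE]
  }
  m1 <- segmentation_mask(blob, 100)
  m2 <- segmentation_mask(rot90(blob), 100)
  expect_equal(plant_volume(m1), plant_volume(m2))
  r1 <- porosity(m1, convex_hull(m1))
  r2 <- porosity(m2, convex_hull(m2))
  expect_equal(r1$porosity, r2$porosity, tolerance = 1e-12)
  expect_equal(r1$hull_volume_mm3, r2$hull_volume_mm3, tolerance = 1e-12)
  expect_equal(surface_area(m1), surface_area(m2))
})

test_that("rasterizing the hull of a rasterized hull is idempotent", {
  blob <- random_blob_mask(c(14, 16, 16), n_balls = 2, seed = 12)
  m <- segmentation_mask(blob, 100)
  r1 <- convex_hull(m)$raster
  r2 <- convex_hull(segmentation_mask(r1, 100))$raster
  expect_identical(r2, r1)
})

test_that("analyze_specimen composes the stages deterministically", {
  ph <- sphere_phantom(r_vox = 12, margin = 4, noise_sd = 10, seed = 21L)
  a1 <- analyze_specimen(ph$grid, config = list(crop_mm = Inf))
  a2 <- analyze_specimen(ph$grid, config = list(crop_mm = Inf))
  expect_identical(a1$result, a2$result)
  expect_s3_class(a1$result, "morphometry_result")
  expect_lte(a1$result$porosity, 0.05)
  # cropping config is honoured
  a3 <- analyze_specimen(ph$grid, config = list(crop_mm = 1.0))
  expect_lt(a3$result$plant_volume_mm3, a1$result$plant_volume_mm3)
  expect_equal(a3$result$crop_height_mm, 1.0)
})

test_that("porosity falls as stems pack a fixed-radius colony", {
  poro <- sapply(c(0.6, 1.2, 1.9), function(dens) {
    ph <- generate_voxel_phantom(phantom_spec(
      "colony_core", grid_dims = c(24, 76, 76), voxel_spacing = 1000,
      core_diameter_um = 73000, stem_density_cm2 = dens,
      stem_length_um = 20000, stem_radius_um = 1600, rng_seed = 7L))
    a <- analyze_specimen(ph$grid, config = list(crop_mm = Inf))
    a$result$porosity
  })
  expect_true(all(diff(poro) < 0))
})

test_that("batches summarise with medians and quartiles per metric", {
  results <- lapply(1:4, function(s) {
    ph <- generate_voxel_phantom(phantom_spec(
      "colony_core", grid_dims = c(10, 60, 60), voxel_spacing = 1250,
      core_diameter_um = 73000, stem_density_cm2 = 1.2,
      stem_length_um = 8000, stem_radius_um = 1800, rng_seed = s))
    analyze_specimen(ph$grid, config = list(crop_mm = Inf))
  })
  s <- summarize_batch(results)
  expect_identical(nrow(s), 5L)
  expect_true(all(s$n == 4))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  poro <- s[s$metric == "porosity", ]
  expect_true(poro$median > 0 && poro$median < 1)
})
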