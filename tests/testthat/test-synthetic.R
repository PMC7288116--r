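test_that("layout validation names the offending field", {
  expect_error(orchard_layout(n_rows = 0), "n_rows")
  expect_error(orchard_layout(row_spacing = -1), "row_spacing")
  expect_error(orchard_layout(dead_fraction = 1), "dead_fraction")
  expect_error(orchard_layout(field_width = 10), "field_width")
  expect_error(orchard_layout(trees_per_row = c(30, 31)), "trees_per_row")
})

test_that("default layout reproduces the 160-tree study block", {
  lay <- orchard_layout()
  trees <- generate_trees(lay, seed = 1)
  expect_equal(nrow(trees), 160L)
  expect_equal(as.vector(table(trees$row)), c(30L, 31L, 32L, 33L, 34L))
  # dead_fraction = 0 gives an all-live orchard
  lay0 <- orchard_layout(dead_fraction = 0)
  expect_false(any(generate_trees(lay0, seed = 1)$is_dead))
})

test_that("tree generation is deterministic in (parameters, seed)", {
  lay <- small_layout(0.2)
  expect_identical(generate_trees(lay, seed = 5), generate_trees(lay, seed = 5))
  expect_false(identical(generate_trees(lay, seed = 5),
                         generate_trees(lay, seed = 6)))
})

test_that("zero-noise yields equal the deterministic signal and dead trees get 0", {
  trees <- generate_trees(small_layout(0.3), seed = 3)
  y0 <- assign_yields(trees, noise_sd = 0, seed = 1)
  expect_equal(y0$yield_kg, y0$yield_signal)
  expect_true(all(y0$yield_kg[y0$is_dead] == 0))
  # every tree dead -> every yield 0
  all_dead <- trees
  all_dead$is_dead <- TRUE
  expect_true(all(assign_yields(all_dead, seed = 1)$yield_kg == 0))
})

test_that("auto noise calibration attains the target R2 at n = 160", {
  trees <- generate_trees(orchard_layout(), seed = 2)
  yy <- assign_yields(trees, noise_sd = "auto", seed = 9, target_r2 = 0.90)
  live <- !yy$is_dead
  r2 <- cor(yy$yield_signal[live], yy$yield_kg[live])^2
  expect_lt(abs(r2 - 0.90), 0.03)
  expect_gt(attr(yy, "noise_sd"), 0)
})

test_that("raster sizing follows ceil(extent * 100 / gsd)", {
  expect_equal(raster_dims(2.13, 140, 25), c(nrow = 1174L, ncol = 6573L))
  expect_error(raster_dims(0, 10, 10), "gsd")
})

test_that("band rendering: constant soil without trees, canopy contrast with", {
  lay <- small_layout()
  none <- generate_trees(lay, seed = 1)[0, ]
  b <- render_bands(none, lay, gsd = 5, noise_sd = 0, seed = 1)
  expect_equal(max(abs(b$gre - 0.18)), 0)
  expect_equal(max(abs(b$nir - 0.30)), 0)

  trees <- generate_trees(lay, seed = 1)
  b2 <- render_bands(trees, lay, gsd = 5, noise_sd = 0, seed = 1)
  # mean NG over soil pixels exceeds mean NG over canopy pixels
  ng <- b2$gre / (b2$nir + b2$red + b2$gre)
  canopy_px <- b2$nir > 0.4
  expect_gt(mean(ng[!canopy_px]), mean(ng[canopy_px]))
  # soil/canopy separation of at least 5 grayscale levels after 0-255 scaling
  b3 <- render_bands(trees, lay, gsd = 5, noise_sd = 0.01, seed = 1)
  ng3 <- compute_index(b3, "NG")
  canopy_px3 <- b3$nir > 0.4
  expect_gte(mean(ng3$gray[!canopy_px3]) - mean(ng3$gray[canopy_px3]), 5)
  expect_error(render_bands(trees, lay, gsd = 0.0001), "max_pixels")
})

test_that("cloud density tracks the calibrated GSD-density map", {
  expect_equal(gsd_point_density(c(2.13, 3.31, 4.39, 5.43, 6.69)),
               c(364.77, 75.55, 32.01, 17.22, 8.65))
  # log-linear interpolation is monotone decreasing in between
  g <- seq(2.2, 6.6, by = 0.1)
  expect_true(all(diff(gsd_point_density(g)) < 0))

  # realized per-canopy density within 10% for a canopy of a few m^3
  lay <- orchard_layout(1, 1, 5, 4, 8, 6, 0)
  tr <- generate_trees(lay, seed = 1)
  tr$height <- 3.4; tr$radius <- 1.5   # volume ~ 6.6 m^3
  cl <- render_cloud(tr, lay, gsd = 2.13, xyz_noise_sd = 0,
                     ground_density = 0, seed = 4)
  vol <- truth_volume(tr$height, tr$radius, tr$trunk_height)
  expect_lt(abs(nrow(cl) / vol - 364.77) / 364.77, 0.10)
})

test_that("cloud geometry: dead trees minimal, vertical span matches truth", {
  lay <- orchard_layout(1, 2, 5, 4, 12, 6, 0)
  tr <- generate_trees(lay, seed = 2)
  tr$is_dead <- c(TRUE, FALSE)
  cl <- render_cloud(tr, lay, gsd = 3.31, xyz_noise_sd = 0,
                     ground_density = 0, seed = 1)
  near_dead <- abs(cl[, "x"] - tr$center_x[1]) < 1
  expect_lte(sum(near_dead), 5)
  live_pts <- cl[abs(cl[, "x"] - tr$center_x[2]) <= tr$radius[2] + 0.01, ]
  expect_equal(max(live_pts[, "z"]) - min(live_pts[, "z"]),
               tr$height[2] - tr$trunk_height[2], tolerance = 0.05)
  expect_error(render_cloud(tr, lay, gsd = 3.31, xyz_noise_sd = -1),
               "xyz_noise_sd")
})

test_that("scenes are reproducible and spatially consistent", {
  s1 <- small_scene()
  s2 <- simulate_scene(small_layout(0.1), gsd = 4.39, seed = 11)
  expect_identical(s1$trees, s2$trees)
  expect_identical(s1$bands$gre, s2$bands$gre)
  expect_identical(unclass(s1$cloud), unclass(s2$cloud))
  # cloud bounding box inside the raster extent (jitter can nudge a point a
  # few cm outside; allow the 3-sigma jitter margin)
  ext <- attr(s1$cloud, "extent")
  expect_equal(unname(ext[["length_m"]]),
               ncol(s1$bands$gre) * s1$gsd / 100)
  expect_true(all(s1$cloud[, "x"] > -0.25 &
                    s1$cloud[, "x"] < ext[["length_m"]] + 0.25))
})
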