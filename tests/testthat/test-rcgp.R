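test_that("projection profiles are exact directional sums", {
  g <- matrix(c(1, 3, 2, 4), 2)   # rows: (1,2), (3,4)
  expect_equal(project_profile(g, "row")$raw, c(3, 7))
  expect_equal(project_profile(g, "column")$raw, c(4, 6))
  expect_equal(project_profile(matrix(0, 3, 3), "row")$raw, rep(0, 3))
  expect_error(project_profile(matrix(numeric(0), 0, 0)), "empty")
})

test_that("kernel smoothing preserves mass and matches the direct oracle", {
  p <- project_profile(matrix(5, 4, 6), "row")
  sm <- smooth_profile(p, h = 2)
  expect_equal(sm$smoothed, sm$raw)        # constants are fixed points
  expect_error(smooth_profile(p, h = 0), "bandwidth")

  # unit impulse reproduces the discrete Gaussian kernel
  x <- c(rep(0, 30), 1, rep(0, 30))
  sm2 <- uavcanopy:::gaussian_smooth(x, 2)
  r <- 8
  k <- dnorm(-r:r, sd = 2); k <- k / sum(k)
  expect_equal(sm2[(31 - r):(31 + r)], k, tolerance = 1e-12)

  set.seed(3)
  for (h in c(0.7, 2, 5.5)) {
    x <- runif(47, 0, 100)
    y <- uavcanopy:::gaussian_smooth(x, h)
    expect_equal(y, oracle_smooth(x, h), tolerance = 1e-9)
    expect_equal(sum(y), sum(x), tolerance = 1e-9)
  }
})

test_that("boundary detection finds bump apexes and handles degenerate profiles", {
  # strictly monotone profile: edges only
  p <- project_profile(matrix(1, 50, 1), "row")
  p$raw <- seq(1, 50)
  p <- smooth_profile(p, 1)
  expect_warning(b <- detect_boundaries(p, min_separation = 5),
                 "no interior")
  expect_equal(b, c(0L, 49L))

  # two well-separated Gaussian bumps: boundaries at the apexes (+-1 px)
  pos <- seq(0, 199)
  prof <- dnorm(pos, 60, 8) + dnorm(pos, 140, 8)
  p2 <- project_profile(matrix(1, 200, 1), "row")
  p2$raw <- prof
  p2 <- smooth_profile(p2, 1)
  b2 <- detect_boundaries(p2, min_separation = 20)
  expect_equal(length(b2), 4L)
  expect_lte(abs(b2[2] - 60), 1)
  expect_lte(abs(b2[3] - 140), 1)

  # scaling intensities leaves boundaries unchanged (relative thresholds)
  p3 <- p2
  p3$raw <- prof * 37.5
  p3 <- smooth_profile(p3, 1)
  expect_equal(detect_boundaries(p3, min_separation = 20), b2)
})

test_that("pixel/metre boundary conversion is proportional and round-trips", {
  expect_equal(boundaries_to_m(500, 1000, 25), 12.5)
  expect_equal(boundaries_to_m(0, 1000, 25), 0)
  set.seed(8)
  b <- sort(runif(12, 0, 999))
  m <- boundaries_to_m(b, 1000, 25)
  back <- boundaries_to_px(m, 1000, 25)
  expect_equal(back, b, tolerance = 1e-10)
  # quantized round-trip stays within one pixel
  expect_true(all(abs(round(back) - b) <= 1))
  expect_error(boundaries_to_m(1, 0, 25), "extents")
})

test_that("scene segmentation detects the planted grid and partitions the cloud", {
  scene <- fixture("seg_scene", function()
    simulate_scene(small_layout(0), gsd = 3.31, seed = 21))
  ng <- compute_index(scene$bands, "NG")
  seg <- segment_scene(ng, cloud = scene$cloud)
  # 3 planted rows -> 2 interior boundaries -> 3 bands
  expect_equal(length(seg$L_2D) - 1L, 3L)
  expect_equal(nrow(seg$regions), nrow(scene$trees))
  # every region holds exactly one truth centre (no dead trees here)
  sc <- score_detection(seg, scene$trees)
  expect_equal(sc$C, 100)
  expect_equal(sc$E, 0)
  # partition property: assigned point counts cover the in-extent cloud
  inext <- sum(!is.na(seg$point_region))
  expect_equal(sum(seg$regions$P), inext)
  expect_gt(inext / nrow(scene$cloud), 0.99)
  # L_3D is the proportional image of L_2D
  expect_equal(seg$L_3D, seg$L_2D * seg$m_3D / seg$m_2D)
})

test_that("detection scores equal the brute-force containment oracle", {
  scene <- fixture("seg_scene_dead", function()
    simulate_scene(small_layout(0.25), gsd = 3.31, seed = 33))
  ng <- compute_index(scene$bands, "NG")
  seg <- segment_scene(ng)
  counts <- oracle_containment(seg, scene$trees)
  sc <- score_detection(seg, scene$trees)
  expect_equal(sc$NC, sum(counts == 1L))
  expect_equal(sc$N, nrow(seg$regions))
  expect_equal(sc$NE, sc$N - sc$NC)
  expect_equal(sc$C, 100 * sc$NC / sc$N)
  expect_equal(sc$E, 100 * sc$NE / sc$N)
  # perturbed truth shifts containment; oracle must track score_detection
  jt <- scene$trees
  set.seed(5)
  jt$center_x <- jt$center_x + runif(nrow(jt), -2, 2)
  jt$center_y <- jt$center_y + runif(nrow(jt), -2, 2)
  sc2 <- score_detection(seg, jt)
  expect_equal(sc2$NC, sum(oracle_containment(seg, jt) == 1L))
})

test_that("detection-rate arithmetic follows the C and E definitions", {
  # NC = 8 of N = 10 regions -> C = 80%
  fake <- list(NC = 8, NE = 2, N = 10)
  expect_equal(100 * fake$NC / fake$N, 80)
  # all regions correct -> C = 100, E = 0 (checked end-to-end above)
  scene <- fixture("seg_scene", function()
    simulate_scene(small_layout(0), gsd = 3.31, seed = 21))
  seg <- segment_scene(compute_index(scene$bands, "NG"))
  sc <- score_detection(seg, scene$trees)
  expect_equal(sc$C + sc$E, 100)
})
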