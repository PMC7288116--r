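test_that("color moments match hand computations and the direct oracle", {
  expect_equal(color_moments(matrix(100, 3, 3)), list(mu = 100, sigma = 0, s = 0))
  cm <- color_moments(matrix(c(0, 0, 0, 200), 2))
  expect_equal(cm$mu, 50)
  expect_equal(cm$sigma, sqrt(7500))
  expect_equal(cm$s, 750000^(1 / 3))
  # symmetric two-level patch has zero third moment
  expect_equal(color_moments(matrix(c(0, 200, 200, 0), 2))$s, 0)
  expect_error(color_moments(matrix(numeric(0))), "empty")
  set.seed(21)
  for (k in 1:20) {
    p <- matrix(sample(0:255, 30, TRUE), 5)
    expect_equal(color_moments(p), oracle_moments(p), tolerance = 1e-12)
  }
})

test_that("moments shift correctly under constant offsets and permutations", {
  set.seed(4)
  p <- matrix(sample(0:200, 48, TRUE), 6)
  cm <- color_moments(p)
  cm2 <- color_moments(p + 30)
  expect_equal(cm2$mu, cm$mu + 30)
  expect_equal(cm2$sigma, cm$sigma)
  expect_equal(cm2$s, cm$s)
  expect_equal(color_moments(matrix(sample(as.vector(p)), 8)), cm)
})

test_that("GLCM counts ordered pairs, normalizes, and quantizes as stated", {
  # alternating 0/1 columns, single rightward offset
  patch <- matrix(rep(c(0, 1, 0, 1), 4), 4, byrow = TRUE)
  p <- glcm(patch, levels = 2, offsets = list(c(0L, 1L)), quantize = FALSE)
  expect_equal(sum(p), 1)
  expect_equal(p[1, 2], 2 / 3)
  expect_equal(p[2, 1], 1 / 3)
  # constant patch concentrates on a single diagonal cell
  pc <- glcm(matrix(1, 4, 4), levels = 2, offsets = list(c(0L, 1L)),
             quantize = FALSE)
  expect_equal(pc[2, 2], 1)
  # quantization: 0..255 -> 16 uniform bins
  pq <- glcm(matrix(c(0, 0, 255, 255), 2), levels = 16,
             offsets = list(c(0L, 1L)))
  expect_equal(pq[1, 16], 1)
  expect_error(glcm(matrix(1, 1, 1), levels = 2, offsets = list(c(0L, 1L)),
                    quantize = FALSE), "offset")
  expect_error(glcm(matrix(1, 2, 2), levels = 1), "levels")
  # any valid patch: probabilities sum to one over the default 4 offsets
  set.seed(9)
  expect_equal(sum(glcm(matrix(sample(0:255, 64, TRUE), 8))), 1)
})

test_that("texture features match the equations and the double-loop oracle", {
  patch <- matrix(rep(c(0, 1, 0, 1), 4), 4, byrow = TRUE)
  p <- glcm(patch, levels = 2, offsets = list(c(0L, 1L)), quantize = FALSE)
  tx <- texture_features(p)
  expect_equal(tx$CON, 1)
  expect_equal(tx$ASM, 5 / 9)
  expect_equal(tx$INM, 1 / 2)
  expect_equal(tx$COR, -1)
  # constant patch: CON 0, ASM 1, INM 1, COR flagged
  tc <- texture_features(glcm(matrix(3, 4, 4), levels = 4,
                              offsets = list(c(0L, 1L)), quantize = FALSE))
  expect_equal(tc$CON, 0)
  expect_equal(tc$ASM, 1)
  expect_equal(tc$INM, 1)
  expect_false(tc$cor_defined)
  set.seed(31)
  for (k in 1:50) {
    patch <- matrix(sample(0:255, 100, TRUE), 10)
    p <- glcm(patch, levels = 8)
    tx <- texture_features(p)
    orc <- oracle_texture(p)
    for (f in c("CON", "COR", "ASM", "INM"))
      expect_equal(tx[[f]], orc[[f]], tolerance = 1e-12, info = f)
    expect_true(tx$ASM > 0 && tx$ASM <= 1)
    expect_true(tx$INM > 0 && tx$INM <= 1)
    expect_gte(tx$CON, 0)
    expect_true(abs(tx$COR) <= 1 + 1e-12)
  }
})

test_that("input modes assemble the documented feature counts", {
  scene <- small_scene()
  imgs <- lapply(vegetation_indices(), function(nm)
    compute_index(scene$bands, nm))
  names(imgs) <- vegetation_indices()
  grays <- lapply(imgs, `[[`, "gray")
  seg <- segment_scene(imgs$NG, cloud = scene$cloud)
  morph <- morph_table(seg)
  feats <- fixture("small_feats", function()
    extract_features(grays, seg, morph))
  expect_equal(ncol(select_input_mode(feats, "input1:NG")), 10L)
  expect_equal(ncol(select_input_mode(feats, "input2")), 4L)
  expect_equal(ncol(select_input_mode(feats, "input3")), 30L)
  expect_equal(ncol(select_input_mode(feats, "input4")), 40L)
  expect_equal(ncol(select_input_mode(feats, "input5")), 70L)
  expect_equal(ncol(select_input_mode(feats, "input6")), 74L)
  expect_error(select_input_mode(feats, "input9"), "unknown")
  expect_error(select_input_mode(feats, "input1:ZZZ"), "unknown")
  # per-region values equal direct patch computation
  r <- 2
  ri <- (seg$regions$r0[r] + 1):seg$regions$r1[r]
  ci <- (seg$regions$c0[r] + 1):seg$regions$c1[r]
  cm <- color_moments(grays$NDVI[ri, ci])
  expect_equal(unname(feats$NDVI_mu[r]), cm$mu)
  expect_equal(unname(feats$NDVI_sigma[r]), cm$sigma)
})
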