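test_that("minmax_normalize maps linearly and handles degeneracy", {
  expect_equal(minmax_normalize(array(c(0, 5, 10), c(3, 1, 1))),
               array(c(0, 0.5, 1), c(3, 1, 1)))
  x <- array(seq(0, 1, length.out = 27), c(3, 3, 3))
  expect_equal(minmax_normalize(x), x)
  expect_warning(out <- minmax_normalize(array(7, c(2, 2, 2))), "constant")
  expect_equal(out, array(0, c(2, 2, 2)))
})

test_that("fat_water_sum is voxelwise addition", {
  d <- c(4L, 4L, 4L)
  fw <- fat_water_volume(array(1, d), array(2, d))
  expect_equal(fat_water_sum(fw), array(3, d))
  fw0 <- fat_water_volume(array(5, d), array(0, d))
  expect_equal(fat_water_sum(fw0), fw0$fat)
  set.seed(0)
  f <- array(runif(prod(d)), d); w <- array(runif(prod(d)), d)
  expect_equal(fat_water_sum(fat_water_volume(f, w)), f + w)
})

test_that("sigmoid_combine evaluates the printed decision function", {
  d <- c(2L, 2L, 2L)
  fw <- fat_water_volume(array(1, d), array(1, d))
  expect_equal(sigmoid_combine(fw)[1], 1 / (1 + exp(-1.25)), tolerance = 1e-12)
  # SI_W = 0, SI_F large: exponent -> 0-, output -> 0.5
  fw2 <- fat_water_volume(array(1e9, d), array(0, d))
  expect_equal(sigmoid_combine(fw2)[1], 0.5, tolerance = 1e-6)
  # SI_F -> 0+ with SI_W = 1: exponent -> -Inf, output -> 1 (epsilon rule)
  f <- array(1, d); f[1, 1, 1] <- 0
  fw3 <- fat_water_volume(f, array(1, d))
  expect_equal(sigmoid_combine(fw3)[1, 1, 1], 1)
  # range and monotonicity in SI_W at fixed SI_F
  set.seed(1)
  fr <- array(runif(prod(d), 0.1, 2), d)
  w1 <- array(runif(prod(d), 0, 2), d)
  s1 <- sigmoid_combine(fat_water_volume(fr, w1))
  s2 <- sigmoid_combine(fat_water_volume(fr, w1 + 0.3))
  expect_true(all(s1 > 0 & s1 <= 1))
  expect_true(all(s2 > s1))
})

test_that("the alternative sigmoid reading is available but off by default", {
  d <- c(2L, 2L, 2L)
  fw <- fat_water_volume(array(2, d), array(1, d))
  alt <- sigmoid_combine(fw, preprocess_config(sigmoid_variant = "offset_scaled"))
  expect_equal(alt[1], 1 / (1 + exp(-(1 - 0.25 * 2) / 2)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(alt[1], sigmoid_combine(fw)[1])))
})

test_that("canny_edges finds shape boundaries and nothing on constants", {
  expect_equal(canny_edges(array(0.5, c(16, 16, 3))), array(0, c(16, 16, 3)))
  img <- array(0, c(32, 32, 1))
  img[9:24, 9:24, 1] <- 1
  e <- canny_edges(img)
  expect_true(all(e %in% c(0, 1)))
  # boundary-set oracle: edges lie within 2 voxels of the rectangle boundary
  # (the Gaussian prefilter widens the ridge) and surround the rectangle
  boundary <- array(FALSE, c(32, 32, 1))
  boundary[7:26, 7:26, 1] <- TRUE
  boundary[11:22, 11:22, 1] <- FALSE
  expect_true(all(boundary[e == 1]))
  expect_gt(sum(e), 40)  # most of the ring is detected
})

test_that("edge_enhance adds half the edge map and clips", {
  x <- array(0.4, c(4, 4, 2)); e <- array(0, c(4, 4, 2))
  expect_equal(edge_enhance(x, e), x)
  e[1, 1, 1] <- 1
  expect_equal(edge_enhance(x, e)[1, 1, 1], 0.9)
  x2 <- array(0.8, c(4, 4, 2))
  expect_equal(edge_enhance(x2, e)[1, 1, 1], 1)
  cfg <- preprocess_config(clip_enhanced = FALSE)
  expect_equal(edge_enhance(x2, e, cfg)[1, 1, 1], 1.3)
  expect_error(edge_enhance(x, array(0, c(2, 2, 2))), "shape")
})

test_that("otsu_threshold separates a bimodal volume and rejects constants", {
  v <- array(rep(c(0.1, 0.9), each = 32), c(4, 4, 4))
  res <- otsu_threshold(v)
  expect_gt(res$threshold, 0.1)
  expect_lt(res$threshold, 0.9)
  expect_equal(res$foreground, array(as.numeric(v > 0.5), dim(v)))
  expect_error(otsu_threshold(array(3, c(4, 4, 4))), "degenerate histogram")
})

test_that("otsu_threshold equals the exhaustive between-class oracle", {
  set.seed(0)
  for (rep in 1:10) {
    v <- array(c(rnorm(400, 0.25, 0.06), rnorm(400, 0.7, 0.1)), c(80, 10, 1))
    expect_equal(otsu_threshold(v)$threshold, otsu_oracle(v), tolerance = 1e-12)
  }
})

test_that("body_mask fills cavities, keeps the largest component, is idempotent", {
  d <- c(24L, 24L, 24L)
  cc <- expand.grid(i = 1:24, j = 1:24, k = 1:24)
  sphere <- array(as.numeric((cc$i - 12)^2 + (cc$j - 12)^2 + (cc$k - 12)^2 <= 64), d)
  cavity <- sphere
  cavity[11:13, 11:13, 11:13] <- 0
  out <- body_mask(cavity)
  expect_true(all(out[sphere == 1] == 1))
  # two components: only the larger survives
  two <- array(0, d)
  two[2:12, 2:12, 2:12] <- 1
  two[20:21, 20:21, 20:21] <- 1
  out2 <- body_mask(two, preprocess_config(closing_radius = 1))
  expect_equal(sum(out2[20:21, 20:21, 20:21]), 0)
  expect_true(all(out2[2:12, 2:12, 2:12] == 1))
  # scattered far-away single-voxel noise cannot survive
  noisy <- sphere
  noisy[1, 1, 1] <- 1; noisy[24, 1, 24] <- 1
  out3 <- body_mask(noisy)
  expect_equal(out3, body_mask(sphere))
  # idempotence
  expect_equal(body_mask(out3), out3)
  expect_error(body_mask(array(0, d)), "empty body region")
})

test_that("preprocess_pipeline recovers the body and zeroes the background", {
  ph <- make_phantom(phantom_spec(seed = 31, noise_sigma = 0))
  pre <- preprocess_pipeline(ph$volume)
  expect_gte(dice_coefficient(pre$body_mask, ph$truth$body_support), 0.95)
  # background voxels outside the body mask are exactly 0
  full <- mirror_merge(pre$right$image, pre$left$image, pre$lr_axis)
  expect_true(all(full[pre$body_mask == 0] == 0))
  # determinism
  pre2 <- preprocess_pipeline(ph$volume)
  expect_identical(pre$right$image, pre2$right$image)
  expect_identical(pre$left$body_mask, pre2$left$body_mask)
})
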