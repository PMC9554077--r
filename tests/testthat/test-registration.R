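test_that("nmi is maximal for identical arrays and ~1 for independent noise", {
  set.seed(0)
  a <- array(runif(40 * 40 * 40), c(40, 40, 40))
  expect_equal(nmi(a, a), 2)
  b <- array(runif(40 * 40 * 40), c(40, 40, 40))
  expect_lt(abs(nmi(a, b, bins = 32L) - 1), 0.05)
  # histogram invariance under a common spatial permutation
  perm <- sample(length(a))
  ap <- array(a[perm], dim(a)); bp <- array(b[perm], dim(b))
  expect_equal(nmi(ap, bp), nmi(a, b))
  expect_error(nmi(array(1, c(4, 4, 4)), a[1:4, 1:4, 1:4, drop = FALSE]),
               "constant")
  expect_error(nmi(a, b[1:10, , , drop = FALSE]), "shape")
})

test_that("select_templates ranks by NMI with deterministic tie-breaking", {
  d <- c(12L, 12L, 12L)
  set.seed(1)
  mk <- function(id, img) {
    m <- array(0, d); m[4:8, 4:8, 4:8] <- 1
    template_pair(id, single_breast_volume(img, array(1, d), side = "right"),
                  segmentation_mask(m))
  }
  imgs <- lapply(1:10, function(i) array(runif(prod(d)), d))
  dict <- template_dictionary(lapply(1:10, function(i)
    mk(paste0("t", i), imgs[[i]])))
  target <- single_breast_volume(imgs[[7]], array(1, d), side = "right")
  ids <- select_templates(target, dict, k = 5L)
  expect_identical(ids[1], "t7")  # exact match ranks first at NMI 2
  # brute-force oracle over all NMI values
  vals <- vapply(imgs, function(im) nmi(target$image, im), numeric(1))
  oracle <- paste0("t", order(-vals)[1:5])
  expect_identical(as.character(ids), oracle)
  # dictionary of exactly k returns everything
  dict5 <- template_dictionary(lapply(1:5, function(i)
    mk(paste0("s", i), imgs[[i]])))
  expect_length(select_templates(target, dict5, k = 5L), 5L)
  expect_error(select_templates(target, dict5, k = 6L), "smaller")
})

test_that("registering a volume onto itself returns (near) identity", {
  ph <- small_phantom(seed = 41)
  pre <- preprocess_pipeline(ph$volume)
  f <- suppressWarnings(register_nonrigid(pre$right, pre$right))
  disp <- sqrt(f$ux^2 + f$uy^2 + f$uz^2)
  expect_lt(median(disp), 0.5)
  expect_gte(attr(f, "nmi_after"), attr(f, "nmi_before"))
})

test_that("warp_mask through identity and translation fields is exact", {
  d <- c(12L, 12L, 12L)
  m <- array(0, d); m[4:7, 5:8, 3:6] <- 1
  mask <- segmentation_mask(m)
  zero <- array(0, d)
  idf <- deformation_field(zero, zero, zero)
  expect_identical(warp_mask(mask, idf)$data, m)
  # field u = +2 along x samples the template at x+2: index-shift oracle
  f2 <- deformation_field(zero + 2, zero, zero)
  w <- warp_mask(mask, f2)$data
  oracle <- array(0, d); oracle[1:10, , ] <- m[3:12, , ]
  expect_identical(w, oracle)
  expect_true(all(w %in% c(0, 1)))
  expect_error(warp_mask(segmentation_mask(array(0, c(4L, 4L, 4L))), idf),
               "grid")
})

test_that("vote_fusion implements the at-least-k counting rule", {
  d <- c(4L, 4L, 4L)
  ones <- segmentation_mask(array(1, d))
  expect_identical(vote_fusion(rep(list(ones), 5))$data, array(1, d))
  # a voxel in exactly 4 of 5 is kept; in exactly 3 of 5 is dropped
  base <- array(0, d)
  m4 <- base; m4[1, 1, 1] <- 1; m4[2, 2, 2] <- 1
  m3 <- base; m3[2, 2, 2] <- 1
  masks <- c(rep(list(segmentation_mask(m4)), 3),
             list(segmentation_mask(m3)),
             list(segmentation_mask(base + m4)))
  fused <- vote_fusion(masks, min_votes = 4L)
  expect_equal(fused$data[1, 1, 1], 1)  # present in 4
  expect_equal(fused$data[2, 2, 2], 1)  # present in 5
  masks3 <- c(rep(list(segmentation_mask(m4)), 3), rep(list(segmentation_mask(base)), 2))
  expect_equal(vote_fusion(masks3, 4L)$data[1, 1, 1], 0)  # only 3 votes
  # counting oracle on random masks
  set.seed(0)
  rnd <- lapply(1:5, function(i)
    segmentation_mask(array(as.numeric(runif(prod(d)) > 0.5), d)))
  counts <- Reduce(`+`, lapply(rnd, `[[`, "data"))
  for (k in 1:5)
    expect_equal(vote_fusion(rnd, k)$data, array(as.numeric(counts >= k), d))
  expect_error(vote_fusion(list()), "empty")
  expect_error(vote_fusion(list(ones, segmentation_mask(array(0, c(2L, 2L, 2L)))),
                           min_votes = 1L),
               "grid")
})

test_that("vote_fusion is monotone and bounded by union/intersection", {
  d <- c(5L, 5L, 5L)
  set.seed(1)
  masks <- lapply(1:5, function(i)
    segmentation_mask(array(as.numeric(runif(prod(d)) > 0.4), d)))
  uni <- Reduce(pmax, lapply(masks, `[[`, "data"))
  int <- Reduce(pmin, lapply(masks, `[[`, "data"))
  prev <- NULL
  for (k in 1:5) {
    f <- vote_fusion(masks, k)$data
    expect_true(all(f <= uni))
    expect_true(all(f >= int * (k <= 5)))
    if (!is.null(prev)) expect_true(all(f <= prev))  # raising k only removes
    prev <- f
  }
  # adding a mask at fixed min_votes can only add voxels
  f4 <- vote_fusion(masks[1:4], 2L)$data
  f5 <- vote_fusion(masks, 2L)$data
  expect_true(all(f5 >= f4))
})

test_that("self-segmentation with a near-duplicate dictionary is exact", {
  ph <- small_phantom(seed = 43)
  pre <- preprocess_pipeline(ph$volume)
  tpl_img <- pre$right
  tpl_mask <- segmentation_mask(split_and_flip(ph$truth$breast_mask_right$data)$right,
                                spacing = c(2, 2, 2))
  set.seed(9)
  perturb <- function(img, eps) {
    single_breast_volume(pmin(pmax(img$image +
      array(rnorm(length(img$image), sd = eps), dim(img$image)) *
        img$body_mask, 0), 1), img$body_mask, side = "right",
      spacing = img$spacing)
  }
  pairs <- lapply(1:5, function(i)
    template_pair(paste0("t", i),
                  if (i == 1) tpl_img else perturb(tpl_img, 0.003),
                  tpl_mask))
  dict <- template_dictionary(pairs)
  res <- suppressWarnings(segment_registration(ph$volume, dict))
  truth_right <- ph$truth$breast_mask_right$data
  expect_gte(dice_coefficient(res$right_mask$data, truth_right), 0.99)
  # containment: outputs lie entirely within the body mask
  body <- preprocess_pipeline(ph$volume)$body_mask
  expect_true(all(res$right_mask$data <= body))
  expect_true(all(res$left_mask$data <= body))
})
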