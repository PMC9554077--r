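test_that("parameter count matches the closed-form layer sum (depth 2, base 8)", {
  m <- build_unet(unet_config(depth = 2L, base_channels = 8L))
  n_params <- sum(vapply(m$params, length, numeric(1)))
  conv <- function(cin, cout, k = 3) k^3 * cin * cout + cout
  bn <- function(c) 2 * c
  blk <- function(cin, cout) conv(cin, cout) + bn(cout) +
    conv(cout, cout) + bn(cout)
  up <- function(cin, cout) 2^3 * cin * cout + cout
  expected <- blk(2, 8) + blk(8, 16) +      # encoder levels
    blk(16, 32) +                           # bottleneck
    up(32, 16) + blk(32, 16) +              # decoder level 2
    up(16, 8) + blk(16, 8) +                # decoder level 1
    conv(8, 1, k = 1)                       # 1x1x1 head
  expect_identical(n_params, expected)
})

test_that("forward pass preserves spatial shape and bounds probabilities", {
  m <- build_unet(unet_config(depth = 2L, base_channels = 4L))
  p <- predict_proba(m, list(fat = array(0, c(16, 16, 16)),
                             water = array(0, c(16, 16, 16))))
  expect_identical(dim(p$data), c(16L, 16L, 16L))
  expect_true(all(p$data >= 0 & p$data <= 1))
  set.seed(4)
  fat <- array(runif(16^3), c(16, 16, 16))
  water <- array(runif(16^3), c(16, 16, 16))
  p1 <- predict_proba(m, list(fat = fat, water = water))
  p2 <- predict_proba(m, list(fat = fat, water = water))
  expect_identical(p1$data, p2$data)  # inference determinism
  expect_error(predict_proba(m, list(fat = array(0, c(15, 16, 16)),
                                     water = array(0, c(15, 16, 16)))),
               "divisible.*pad")
})

test_that("analytic gradients match finite differences", {
  m <- build_unet(unet_config(depth = 2L, base_channels = 4L, seed = 3L))
  set.seed(2)
  xs <- array(runif(16 * 16 * 16 * 2), c(16, 16, 16, 2))
  g <- as.numeric(runif(16^3) > 0.7)
  for (loss in c("dice", "bce")) {
    fw <- dixonseg:::unet_forward(m, xs)
    ls <- dixonseg:::unet_loss(as.numeric(fw$p), g, loss)
    grads <- dixonseg:::unet_backward(m, fw, matrix(ls$dp, ncol = 1))
    for (nm in c("enc1_conv1_W", "bot_bn1_gamma", "dec2_up_W", "final_W")) {
      i <- which.max(abs(grads[[nm]]))
      eps <- 1e-5
      m2 <- m
      m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      fw2 <- dixonseg:::unet_forward(m2, xs)
      l2 <- dixonseg:::unet_loss(as.numeric(fw2$p), g, loss)$loss
      expect_equal(grads[[nm]][i], (l2 - ls$loss) / eps, tolerance = 1e-3)
    }
  }
})

test_that("the plateau LR schedule follows the published recipe on stub losses", {
  cfg <- unet_config(depth = 2L, base_channels = 4L, lr_initial = 1e-3)
  st <- make_train_state(cfg)
  # constant validation loss: first observation counts as the improvement
  st <- update_train_state(st, 1.0, cfg)
  expect_equal(st$lr, 1e-3)
  for (i in 1:49) st <- update_train_state(st, 1.0, cfg)
  expect_equal(st$lr, 1e-3)            # 49 stagnant epochs: no decay yet
  st <- update_train_state(st, 1.0, cfg)
  expect_equal(st$lr, 1e-3 * 0.33)     # exactly 50 stagnant epochs
  # the LR never drops below the floor
  for (i in 1:500) st <- update_train_state(st, 1.0, cfg)
  expect_gte(st$lr, 1e-5)
  expect_equal(st$lr, 1e-5)
})

test_that("early stopping halts exactly 200 epochs after the last improvement", {
  cfg <- unet_config(depth = 2L, base_channels = 4L)
  st <- make_train_state(cfg)
  st <- update_train_state(st, 0.9, cfg)   # improvement at epoch 1
  st <- update_train_state(st, 0.5, cfg)   # improvement at epoch 2
  for (i in 1:199) {
    st <- update_train_state(st, 0.5, cfg)
    expect_false(st$stop)
  }
  st <- update_train_state(st, 0.5, cfg)   # epoch 2 + 200
  expect_true(st$stop)
  expect_equal(st$epoch, 202L)
  expect_equal(st$best_val, 0.5)
})

test_that("training with a fixed seed is run-to-run reproducible", {
  set.seed(11)
  d <- c(16L, 16L, 16L)
  mk <- function() {
    msk <- array(0, d); msk[5:12, 5:12, 5:12] <- 1
    list(fat = array(runif(prod(d)), d) + msk,
         water = array(runif(prod(d)), d) + 2 * msk, mask = msk)
  }
  samples <- list(mk(), mk(), mk())
  cfg <- unet_config(depth = 2L, base_channels = 4L, max_epochs = 2L, seed = 5L)
  f1 <- train_unet(build_unet(cfg), samples[1:2], samples[3], cfg)
  f2 <- train_unet(build_unet(cfg), samples[1:2], samples[3], cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
})

test_that("threshold_and_fill applies the 0.35 decision rule and fills holes", {
  d <- c(8L, 8L, 3L)
  p <- array(0, d)
  p[2, 2, 1] <- 0.36
  p[3, 3, 1] <- 0.34
  m <- threshold_and_fill(probability_map(p), 0.35)
  expect_equal(m$data[2, 2, 1], 1)
  expect_equal(m$data[3, 3, 1], 0)
  # interior cavity in a thresholded ring is filled per slice
  ring <- array(0, d)
  ring[2:7, 2:7, 2] <- 0.9
  ring[4:5, 4:5, 2] <- 0.1
  mf <- threshold_and_fill(probability_map(ring), 0.35)
  expect_true(all(mf$data[4:5, 4:5, 2] == 1))
  # all-zero map stays empty; threshold domain enforced
  expect_equal(sum(threshold_and_fill(probability_map(array(0, d)))$data), 0)
  expect_error(threshold_and_fill(probability_map(p), 1.2), "\\(0, 1\\)")
  # monotone in thr before filling: raising thr never adds voxels
  set.seed(3)
  q <- probability_map(array(runif(prod(d)), d))
  lo <- (q$data > 0.2); hi <- (q$data > 0.6)
  expect_true(all(hi <= lo))
})
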