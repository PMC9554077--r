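# Miniature 3D U-Net for breast segmentation: dual-channel fat/water input,
# [conv3x3x3 + ReLU + BN] x2 per level, 2x2x2 max pooling, transposed-conv
# upsampling with skip concatenation, 1x1x1 head with sigmoid output.
# Implemented in base R matrix algebra (im2col convolutions) with Adam and
# the published plateau learning-rate schedule; sized for phantom-scale
# volumes, not clinical training.

#' U-Net configuration
#'
#' Architecture and training-schedule parameters. The schedule follows the
#' published recipe: Adam, learning rate multiplied by `lr_factor` (0.33)
#' after `lr_patience_epochs` (50) epochs without validation improvement,
#' floored at `lr_floor` (1e-5), and early stopping after
#' `early_stop_epochs` (200) epochs without improvement.
#'
#' @param depth Encoder levels (>= 2); input spatial dims must be divisible
#'   by `2^depth`.
#' @param base_channels Channels of the first level (>= 4), doubling per level.
#' @param batch_size Volumes per optimizer step (default 3).
#' @param lr_initial Initial learning rate.
#' @param lr_factor Plateau decay factor (0.33).
#' @param lr_patience_epochs Stagnant epochs before an LR decay (50).
#' @param lr_floor Minimum learning rate (1e-5).
#' @param early_stop_epochs Stagnant epochs before stopping (200).
#' @param max_epochs Hard epoch cap for miniature runs.
#' @param loss_name `"dice"`, `"bce"`, or `"dice+bce"`.
#' @param final_relu Insert the printed ReLU between the 1x1x1 head and the
#'   sigmoid. Off by default: ReLU-then-sigmoid cannot produce probabilities
#'   below 0.5, which would make the 0.35 decision threshold vacuous.
#' @param seed RNG seed governing initialization and shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 32L, batch_size = 3L,
                        lr_initial = 1e-3, lr_factor = 0.33,
                        lr_patience_epochs = 50L, lr_floor = 1e-5,
                        early_stop_epochs = 200L, max_epochs = 1000L,
                        loss_name = c("dice", "bce", "dice+bce"),
                        final_relu = FALSE, seed = 1L) {
  stopifnot(depth >= 2, base_channels >= 4, lr_floor < lr_initial,
            batch_size >= 1, lr_factor > 0, lr_factor < 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_factor = lr_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 lr_floor = lr_floor,
                 early_stop_epochs = as.integer(early_stop_epochs),
                 max_epochs = as.integer(max_epochs),
                 loss_name = match.arg(loss_name),
                 final_relu = isTRUE(final_relu),
                 seed = as.integer(seed)),
            class = "unet_config")
}

# ---- layer primitives -------------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  px <- nx + 2L; py <- ny + 2L
  vox <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  idx <- matrix(0L, nrow(vox), 27L)
  o <- 0L
  for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
    o <- o + 1L
    idx[, o] <- (vox$i + di) + px * ((vox$j + dj - 1L) + py * (vox$k + dk - 1L))
  }
  .im2col_cache[[key]] <- idx
  idx
}

# x: (nx,ny,nz,C) array -> list(out matrix (nvox x Cout), cache)
conv3_forward <- function(x, W, b) {
  d <- dim(x)[1:3]; C <- dim(x)[4]
  cout <- dim(W)[5]
  xp <- array(0, c(d + 2L, C))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  xpm <- matrix(xp, ncol = C)
  idx <- im2col_idx(d)
  nvox <- nrow(idx)
  Xcol <- matrix(0, nvox, 27L * C)
  for (o in 1:27) Xcol[, (seq_len(C) - 1L) * 27L + o] <- xpm[idx[, o], ]
  Wm <- matrix(W, 27L * C, cout)
  y <- Xcol %*% Wm
  for (co in seq_len(cout)) y[, co] <- y[, co] + b[co]
  list(out = y, cache = list(Xcol = Xcol, Wm = Wm, d = d, C = C, cout = cout))
}

conv3_backward <- function(dy, cache) {
  dW <- crossprod(cache$Xcol, dy)
  db <- colSums(dy)
  dXcol <- dy %*% t(cache$Wm)
  d <- cache$d; C <- cache$C
  idx <- im2col_idx(d)
  npad <- prod(d + 2L)
  dxpm <- matrix(0, npad, C)
  cols <- (seq_len(C) - 1L) * 27L
  for (o in 1:27) dxpm[idx[, o], ] <- dxpm[idx[, o], ] + dXcol[, cols + o]
  dxp <- array(dxpm, c(d + 2L, C))
  dx <- dxp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
  list(dx = dx, dW = array(dW, c(3L, 3L, 3L, C, cache$cout)), db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

# batch norm over all voxels of the volume, per channel (instance-style)
bn_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

bn_backward <- function(dy, cache) {
  N <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2L, s1 / N) - sweep(xhat, 2L, s2 / N, `*`)
  dx <- sweep(dx, 2L, cache$invstd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_axis <- function(x, axis) {
  perm <- c(axis, setdiff(seq_along(dim(x)), axis))
  xp <- aperm(x, perm)
  n <- dim(xp)[1]
  a <- xp[seq(1L, n, 2L), , , , drop = FALSE]
  b <- xp[seq(2L, n, 2L), , , , drop = FALSE]
  sel <- a >= b
  list(out = aperm(pmax(a, b), order(perm)), sel = sel, perm = perm, n = n)
}

unpool_axis <- function(dm, cache) {
  dmp <- aperm(dm, cache$perm)
  out <- array(0, c(cache$n, dim(dmp)[-1]))
  out[seq(1L, cache$n, 2L), , , ] <- dmp * cache$sel
  out[seq(2L, cache$n, 2L), , , ] <- dmp * !cache$sel
  aperm(out, order(cache$perm))
}

maxpool_forward <- function(x) {
  c1 <- pool_axis(x, 1L); c2 <- pool_axis(c1$out, 2L); c3 <- pool_axis(c2$out, 3L)
  list(out = c3$out, cache = list(c1, c2, c3))
}

maxpool_backward <- function(dy, cache) {
  dy <- unpool_axis(dy, cache[[3]])
  dy <- unpool_axis(dy, cache[[2]])
  unpool_axis(dy, cache[[1]])
}

upconv_forward <- function(x, W, b) {
  d <- dim(x)[1:3]; cin <- dim(x)[4]; cout <- dim(W)[5]
  Xm <- matrix(x, ncol = cin)
  out <- array(0, c(2L * d, cout))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    Wo <- matrix(W[di + 1L, dj + 1L, dk + 1L, , ], cin, cout)
    Yo <- Xm %*% Wo
    out[seq(1L, 2L * d[1], 2L) + di, seq(1L, 2L * d[2], 2L) + dj,
        seq(1L, 2L * d[3], 2L) + dk, ] <- array(Yo, c(d, cout))
  }
  for (co in seq_len(cout)) out[, , , co] <- out[, , , co] + b[co]
  list(out = out, cache = list(Xm = Xm, W = W, d = d, cin = cin, cout = cout))
}

upconv_backward <- function(dy, cache) {
  d <- cache$d; cin <- cache$cin; cout <- cache$cout
  dW <- array(0, dim(cache$W))
  dXm <- matrix(0, nrow(cache$Xm), cin)
  db <- numeric(cout)
  for (co in seq_len(cout)) db[co] <- sum(dy[, , , co])
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    block <- dy[seq(1L, 2L * d[1], 2L) + di, seq(1L, 2L * d[2], 2L) + dj,
                seq(1L, 2L * d[3], 2L) + dk, , drop = FALSE]
    dYo <- matrix(block, ncol = cout)
    Wo <- matrix(cache$W[di + 1L, dj + 1L, dk + 1L, , ], cin, cout)
    dW[di + 1L, dj + 1L, dk + 1L, , ] <- crossprod(cache$Xm, dYo)
    dXm <- dXm + dYo %*% t(Wo)
  }
  list(dx = array(dXm, c(d, cin)), dW = dW, db = db)
}

# ---- model ------------------------------------------------------------------

unet_channel_plan <- function(cfg) {
  depth <- cfg$depth; base <- cfg$base_channels
  enc <- lapply(seq_len(depth), function(l) {
    cin <- if (l == 1L) 2L else base * 2L^(l - 2L)
    list(cin = cin, cout = base * 2L^(l - 1L))
  })
  bot <- list(cin = base * 2L^(depth - 1L), cout = base * 2L^depth)
  dec <- lapply(rev(seq_len(depth)), function(l) {
    above <- if (l == depth) bot$cout else base * 2L^l
    skip <- base * 2L^(l - 1L)
    list(level = l, above = above, skip = skip)
  })
  list(enc = enc, bot = bot, dec = dec)
}

init_conv <- function(cin, cout, k = 3L) {
  fan_in <- k^3 * cin
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
        c(k, k, k, cin, cout))
}

#' Build a 3D U-Net model
#'
#' Two input channels (fat-only and water-only images); per encoder level two
#' 3x3x3 padded convolutions each followed by ReLU and batch normalization,
#' then 2x2x2 max pooling; a double-conv bottleneck; per decoder level a
#' 2x2x2 transposed convolution, concatenation of the same-size encoder
#' feature map, and two conv-ReLU-BN blocks; finally a 1x1x1 convolution with
#' a sigmoid producing the per-voxel breast probability. Channel widths
#' double per level from `base_channels`. Initialization is seeded (He).
#'
#' @param cfg A [unet_config].
#' @return An object of class `unet_model` holding the parameter list and
#'   config.
#' @export
build_unet <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  plan <- unet_channel_plan(cfg)
  block_params <- function(prefix, cin, cout) {
    setNames(list(init_conv(cin, cout), numeric(cout), rep(1, cout),
                  numeric(cout), init_conv(cout, cout), numeric(cout),
                  rep(1, cout), numeric(cout)),
             paste0(prefix, c("_conv1_W", "_conv1_b", "_bn1_gamma",
                              "_bn1_beta", "_conv2_W", "_conv2_b",
                              "_bn2_gamma", "_bn2_beta")))
  }
  params <- with_seed(cfg$seed, {
    out <- list()
    for (l in seq_len(cfg$depth))
      out <- c(out, block_params(paste0("enc", l), plan$enc[[l]]$cin,
                                 plan$enc[[l]]$cout))
    out <- c(out, block_params("bot", plan$bot$cin, plan$bot$cout))
    for (dl in plan$dec) {
      l <- dl$level
      up <- setNames(list(array(rnorm(8L * dl$above * dl$skip,
                                      sd = sqrt(2 / dl$above)),
                                c(2L, 2L, 2L, dl$above, dl$skip)),
                          numeric(dl$skip)),
                     paste0("dec", l, c("_up_W", "_up_b")))
      out <- c(out, up, block_params(paste0("dec", l), 2L * dl$skip, dl$skip))
    }
    c(out, list(final_W = init_conv(cfg$base_channels, 1L, k = 1L),
                final_b = numeric(1L)))
  })
  structure(list(cfg = cfg, params = params, plan = plan),
            class = "unet_model")
}

# double conv block forward: x is (nx,ny,nz,C) array; returns array out
block_forward <- function(x, params, prefix) {
  d <- dim(x)[1:3]
  c1 <- conv3_forward(x, params[[paste0(prefix, "_conv1_W")]],
                      params[[paste0(prefix, "_conv1_b")]])
  r1 <- relu_forward(c1$out)
  b1 <- bn_forward(r1$out, params[[paste0(prefix, "_bn1_gamma")]],
                   params[[paste0(prefix, "_bn1_beta")]])
  x1 <- array(b1$out, c(d, ncol(b1$out)))
  c2 <- conv3_forward(x1, params[[paste0(prefix, "_conv2_W")]],
                      params[[paste0(prefix, "_conv2_b")]])
  r2 <- relu_forward(c2$out)
  b2 <- bn_forward(r2$out, params[[paste0(prefix, "_bn2_gamma")]],
                   params[[paste0(prefix, "_bn2_beta")]])
  list(out = array(b2$out, c(d, ncol(b2$out))),
       cache = list(c1 = c1, r1 = r1, b1 = b1, c2 = c2, r2 = r2, b2 = b2,
                    d = d))
}

block_backward <- function(dy, cache, prefix, grads) {
  dym <- matrix(dy, ncol = dim(dy)[4])
  g2 <- bn_backward(dym, cache$b2$cache)
  grads[[paste0(prefix, "_bn2_gamma")]] <- g2$dgamma
  grads[[paste0(prefix, "_bn2_beta")]] <- g2$dbeta
  dr2 <- relu_backward(g2$dx, cache$r2$cache)
  cb2 <- conv3_backward(dr2, cache$c2$cache)
  grads[[paste0(prefix, "_conv2_W")]] <- cb2$dW
  grads[[paste0(prefix, "_conv2_b")]] <- cb2$db
  dx1 <- matrix(cb2$dx, ncol = dim(cb2$dx)[4])
  g1 <- bn_backward(dx1, cache$b1$cache)
  grads[[paste0(prefix, "_bn1_gamma")]] <- g1$dgamma
  grads[[paste0(prefix, "_bn1_beta")]] <- g1$dbeta
  dr1 <- relu_backward(g1$dx, cache$r1$cache)
  cb1 <- conv3_backward(dr1, cache$c1$cache)
  grads[[paste0(prefix, "_conv1_W")]] <- cb1$dW
  grads[[paste0(prefix, "_conv1_b")]] <- cb1$db
  list(dx = cb1$dx, grads = grads)
}

unet_forward <- function(model, x) {
  cfg <- model$cfg; params <- model$params
  d <- dim(x)[1:3]
  if (any(d %% 2L^cfg$depth != 0L))
    stop("input spatial dims must be divisible by 2^depth; pad the volume")
  skips <- list(); caches <- list()
  cur <- x
  for (l in seq_len(cfg$depth)) {
    bf <- block_forward(cur, params, paste0("enc", l))
    skips[[l]] <- bf$out
    mp <- maxpool_forward(bf$out)
    caches[[paste0("enc", l)]] <- list(block = bf$cache, pool = mp$cache)
    cur <- mp$out
  }
  bf <- block_forward(cur, params, "bot")
  caches[["bot"]] <- bf$cache
  cur <- bf$out
  for (l in rev(seq_len(cfg$depth))) {
    up <- upconv_forward(cur, params[[paste0("dec", l, "_up_W")]],
                         params[[paste0("dec", l, "_up_b")]])
    skip <- skips[[l]]
    cat_in <- array(0, c(dim(up$out)[1:3], dim(up$out)[4] + dim(skip)[4]))
    cat_in[, , , seq_len(dim(up$out)[4])] <- up$out
    cat_in[, , , dim(up$out)[4] + seq_len(dim(skip)[4])] <- skip
    bf <- block_forward(cat_in, params, paste0("dec", l))
    caches[[paste0("dec", l)]] <- list(up = up$cache, block = bf$cache,
                                       n_up = dim(up$out)[4],
                                       n_skip = dim(skip)[4])
    cur <- bf$out
  }
  zm <- matrix(cur, ncol = dim(cur)[4]) %*%
    matrix(params$final_W, ncol = 1L)
  zm <- zm + params$final_b
  relu_cache <- NULL
  if (cfg$final_relu) {
    rc <- relu_forward(zm)
    relu_cache <- rc$cache
    zm <- rc$out
  }
  p <- 1 / (1 + exp(-zm))
  caches[["final"]] <- list(feat = cur, p = p, relu = relu_cache)
  list(p = array(p, d), caches = caches)
}

unet_backward <- function(model, fw_out, dp) {
  cfg <- model$cfg; params <- model$params
  caches <- fw_out$caches
  grads <- list()
  fin <- caches$final
  dz <- dp * fin$p * (1 - fin$p)
  if (cfg$final_relu) dz <- relu_backward(dz, fin$relu)
  feat_m <- matrix(fin$feat, ncol = dim(fin$feat)[4])
  grads$final_W <- array(crossprod(feat_m, dz), dim(params$final_W))
  grads$final_b <- sum(dz)
  dcur <- array(dz %*% t(matrix(params$final_W, ncol = 1L)),
                dim(fin$feat))
  dskips <- list()
  for (l in seq_len(cfg$depth)) {
    cc <- caches[[paste0("dec", l)]]
    bb <- block_backward(dcur, cc$block, paste0("dec", l), grads)
    grads <- bb$grads
    dcat <- bb$dx
    dup <- dcat[, , , seq_len(cc$n_up), drop = FALSE]
    dskips[[l]] <- dcat[, , , cc$n_up + seq_len(cc$n_skip), drop = FALSE]
    ub <- upconv_backward(dup, cc$up)
    grads[[paste0("dec", l, "_up_W")]] <- ub$dW
    grads[[paste0("dec", l, "_up_b")]] <- ub$db
    dcur <- ub$dx
  }
  bb <- block_backward(dcur, caches$bot, "bot", grads)
  grads <- bb$grads
  dcur <- bb$dx
  for (l in rev(seq_len(cfg$depth))) {
    cc <- caches[[paste0("enc", l)]]
    dpool <- maxpool_backward(dcur, cc$pool)
    dtot <- dpool + dskips[[l]]
    bb <- block_backward(dtot, cc$block, paste0("enc", l), grads)
    grads <- bb$grads
    dcur <- bb$dx
  }
  grads
}

# ---- loss -------------------------------------------------------------------

dice_loss <- function(p, g, eps = 1) {
  num <- 2 * sum(p * g) + eps
  den <- sum(p) + sum(g) + eps
  list(loss = 1 - num / den,
       dp = -(2 * g * den - num) / den^2)
}

bce_loss <- function(p, g) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  n <- length(p)
  list(loss = -mean(g * log(pc) + (1 - g) * log(1 - pc)),
       dp = (pc - g) / (pc * (1 - pc)) / n)
}

unet_loss <- function(p, g, loss_name) {
  switch(loss_name,
         dice = dice_loss(p, g),
         bce = bce_loss(p, g),
         `dice+bce` = {
           a <- dice_loss(p, g); b <- bce_loss(p, g)
           list(loss = a$loss + b$loss, dp = a$dp + b$dp)
         })
}

# ---- training schedule state ------------------------------------------------

#' Initialize a training state
#'
#' @param cfg A [unet_config].
#' @return A `train_state` list tracking epoch, best validation loss,
#'   stagnation counters, and the current learning rate.
#' @export
make_train_state <- function(cfg) {
  structure(list(epoch = 0L, best_val = Inf, since_improve = 0L,
                 since_lr = 0L, lr = cfg$lr_initial, stop = FALSE,
                 improved = FALSE),
            class = "train_state")
}

#' Advance the training state by one validation epoch
#'
#' Implements the plateau schedule: strict improvement of the validation loss
#' resets the stagnation counters; after `lr_patience_epochs` stagnant epochs
#' the learning rate is multiplied by `lr_factor` (never below `lr_floor`);
#' after `early_stop_epochs` stagnant epochs `stop` becomes `TRUE`.
#'
#' @param state A `train_state`.
#' @param val_loss This epoch's validation loss.
#' @param cfg A [unet_config].
#' @return The updated state.
#' @export
update_train_state <- function(state, val_loss, cfg) {
  state$epoch <- state$epoch + 1L
  if (is.na(val_loss)) stop("NaN validation loss")
  if (val_loss < state$best_val) {
    state$best_val <- val_loss
    state$since_improve <- 0L
    state$since_lr <- 0L
    state$improved <- TRUE
  } else {
    state$since_improve <- state$since_improve + 1L
    state$since_lr <- state$since_lr + 1L
    state$improved <- FALSE
  }
  if (state$since_lr >= cfg$lr_patience_epochs && state$lr > cfg$lr_floor) {
    state$lr <- max(state$lr * cfg$lr_factor, cfg$lr_floor)
    state$since_lr <- 0L
  }
  if (state$since_improve >= cfg$early_stop_epochs) state$stop <- TRUE
  state
}

# ---- training ---------------------------------------------------------------

prepare_input <- function(fat, water) {
  nf <- suppressWarnings(minmax_normalize(fat))
  nw <- suppressWarnings(minmax_normalize(water))
  x <- array(0, c(dim(fat), 2L))
  x[, , , 1L] <- nf
  x[, , , 2L] <- nw
  x
}

sample_input <- function(s) prepare_input(s$fat, s$water)

#' Train a U-Net on (fat, water, mask) volumes
#'
#' Adam optimization with the plateau learning-rate schedule and early
#' stopping; the best model by validation loss is retained. Fully seeded
#' (initialization, shuffling). Each sample is a `list(fat, water, mask)` of
#' 3D arrays on a grid divisible by `2^depth`; fat and water are min-max
#' normalized internally.
#'
#' @param model A [build_unet] model.
#' @param train_set,val_set Non-empty lists of samples.
#' @param cfg A [unet_config].
#' @return A list: `model` (best-validation parameters), `state`
#'   (final `train_state`), and `history` (per-epoch train/val loss and LR).
#' @export
train_unet <- function(model, train_set, val_set, cfg = model$cfg) {
  stopifnot(inherits(model, "unet_model"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("empty training or validation set")
  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  adam_t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  state <- make_train_state(cfg)
  best_params <- params
  history <- list()
  xs_train <- lapply(train_set, sample_input)
  gs_train <- lapply(train_set, function(s) as.numeric(s$mask))
  xs_val <- lapply(val_set, sample_input)
  gs_val <- lapply(val_set, function(s) as.numeric(s$mask))

  val_loss_of <- function(mdl) {
    mean(vapply(seq_along(xs_val), function(i) {
      p <- unet_forward(mdl, xs_val[[i]])$p
      unet_loss(as.numeric(p), gs_val[[i]], cfg$loss_name)$loss
    }, numeric(1)))
  }

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(seq_along(xs_train))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      train_losses <- c()
      for (bt in batches) {
        acc <- NULL
        for (i in bt) {
          fw <- unet_forward(model, xs_train[[i]])
          ls <- unet_loss(as.numeric(fw$p), gs_train[[i]], cfg$loss_name)
          if (!is.finite(ls$loss)) stop("NaN training loss")
          train_losses <- c(train_losses, ls$loss)
          dp <- matrix(ls$dp, ncol = 1L)
          g <- unet_backward(model, fw, dp)
          acc <- if (is.null(acc)) g else
            Map(function(a, b) a + b, acc, g[names(acc)])
        }
        adam_t <- adam_t + 1L
        for (nm in names(params)) {
          gr <- acc[[nm]] / length(bt)
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
          mhat <- adam_m[[nm]] / (1 - beta1^adam_t)
          vhat <- adam_v[[nm]] / (1 - beta2^adam_t)
          params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + adam_eps)
        }
        model$params <- params
      }
      vl <- val_loss_of(model)
      if (!is.finite(vl)) stop("NaN validation loss")
      state <- update_train_state(state, vl, cfg)
      if (state$improved) best_params <- params
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = mean(train_losses),
                                     val_loss = vl, lr = state$lr)
      if (state$stop) break
    }
  })
  model$params <- best_params
  list(model = model, state = state, history = do.call(rbind, history))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a breast probability map
#'
#' Runs the network on a fat/water pair preprocessed identically to training
#' (per-volume min-max normalization of each channel). Deterministic: batch
#' normalization uses per-volume statistics.
#'
#' @param model A trained [build_unet] model (or the `model` element of
#'   [train_unet] output).
#' @param fw A [fat_water_volume], or a `list(fat, water)` of arrays.
#' @return A [probability_map].
#' @export
predict_proba <- function(model, fw) {
  if (inherits(model, "unet_model")) m <- model else m <- model$model
  fat <- if (inherits(fw, "fat_water_volume")) fw$fat else fw$fat
  water <- fw$water
  p <- unet_forward(m, prepare_input(fat, water))$p
  probability_map(p)
}

#' Threshold a probability map and fill holes
#'
#' `mask = (p > thr)` followed by per-slice morphological hole filling; the
#' published decision threshold is 0.35. An all-zero map stays empty.
#'
#' @param p A [probability_map].
#' @param thr Threshold in the open interval (0, 1).
#' @param spacing Voxel spacing for the resulting mask.
#' @return A [segmentation_mask].
#' @export
threshold_and_fill <- function(p, thr = 0.35, spacing = c(1, 1, 1)) {
  stopifnot(inherits(p, "probability_map"))
  if (thr <= 0 || thr >= 1) stop("threshold must lie in (0, 1)")
  m <- array(as.numeric(p$data > thr), dim(p$data))
  if (sum(m) > 0) m <- fill_holes_slices(m)
  segmentation_mask(m, spacing = spacing)
}
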