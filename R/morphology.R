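# Internal image-processing primitives: morphology, connected components,
# separable Gaussian smoothing, and 2D Canny edge detection.

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  keep <- g$di^2 + g$dj^2 + g$dk^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(di = -r:r, dj = -r:r, dk = 0L)
  keep <- g$di^2 + g$dj^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

binary_dilate <- function(mask, offsets) {
  d <- dim(mask)
  array(cpp_binary_morph(as.integer(mask != 0), as.integer(d),
                         offsets, TRUE), d)
}

binary_erode <- function(mask, offsets) {
  d <- dim(mask)
  array(cpp_binary_morph(as.integer(mask != 0), as.integer(d),
                         offsets, FALSE), d)
}

# exact closing on an implicitly infinite background: pad by the element
# radius so dilation can spill over the array edge before erosion
binary_close <- function(mask, offsets) {
  r <- max(abs(offsets))
  d <- dim(mask)
  padded <- array(0, d + 2L * r)
  padded[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- mask
  closed <- binary_erode(binary_dilate(padded, offsets), offsets)
  closed[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]), drop = FALSE]
}

fill_holes_slices <- function(mask) {
  d <- dim(mask)
  array(cpp_fill_holes_2d(as.integer(mask != 0), as.integer(d)), d)
}

label_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  array(cpp_label_components(as.integer(mask != 0), as.integer(d),
                             as.integer(connectivity)), d)
}

largest_component <- function(mask, connectivity = 6L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(0, dim(mask)))
  counts <- tabulate(lab[lab > 0L])
  array(as.numeric(lab == which.max(counts)), dim(mask))
}

# Separable 1D Gaussian convolution along one axis (reflected boundary).
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(x, kernel, axis) {
  d <- dim(x)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  n <- d[axis]
  m <- matrix(xp, nrow = n)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  if (r > n) {  # degenerate tiny axis: clamp-pad
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  }
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (o in seq_along(kernel)) {
    out <- out + kernel[o] * mp[(o - 1L) + seq_len(n), , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

gaussian_smooth <- function(x, sigma, axes = 1:3) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  for (ax in axes) x <- convolve_axis(x, k, ax)
  x
}

# 2D Canny edge detection on one slice (matrix): Gaussian smoothing, central
# difference gradients, non-maximum suppression along the quantized gradient
# direction, and double-threshold hysteresis (8-connected).
canny_slice <- function(img, sigma, low_frac, high_frac) {
  d <- dim(img)
  a <- array(img, c(d, 1L))
  a <- gaussian_smooth(a, sigma, axes = 1:2)
  sm <- a[, , 1L]
  nx <- nrow(sm); ny <- ncol(sm)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (sm[3:nx, ] - sm[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (sm[, 3:ny] - sm[, 1:(ny - 2)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, nx, ny))
  # quantize direction into 4 sectors (0, 45, 90, 135 degrees)
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  shift2 <- function(m, di, dj) {
    out <- matrix(0, nx, ny)
    si <- max(1, 1 + di):min(nx, nx + di)
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  nms <- matrix(FALSE, nx, ny)
  dirs <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  for (s in 0:3) {
    dd <- dirs[[as.character(s)]]
    fwd <- shift2(mag, dd[1], dd[2])
    bwd <- shift2(mag, -dd[1], -dd[2])
    nms <- nms | (sector == s & mag >= fwd & mag >= bwd)
  }
  strong <- nms & (mag >= high_frac * mmax)
  weak <- nms & (mag >= low_frac * mmax)
  if (!any(strong)) return(matrix(0, nx, ny))
  lab <- label_components(array(as.numeric(weak), c(nx, ny, 1L)),
                          connectivity = 26L)[, , 1L]
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  out <- matrix(0, nx, ny)
  out[lab %in% keep] <- 1
  out
}
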