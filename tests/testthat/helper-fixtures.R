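# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# the 15-template phantom dictionary shared by the end-to-end acceptance tests
fixture_dictionary <- function() {
  if (is.null(.fixture_env$dict))
    .fixture_env$dict <- make_dictionary(15, phantom_spec(seed = 100))
  .fixture_env$dict
}

# small bilateral phantom for fast module-level tests
small_phantom <- function(seed = 1, ...) {
  make_phantom(phantom_spec(shape = c(32L, 32L, 32L),
                            breast_radius_range = c(6, 8),
                            seed = seed, ...))
}

# a 32^3 single-sided U-Net training sample derived from a phantom
unet_sample <- function(seed) {
  sp <- phantom_spec(shape = c(64L, 32L, 32L), breast_radius_range = c(7, 10),
                     density_fraction = 0.3, seed = seed)
  ph <- make_phantom(sp)
  list(fat = split_and_flip(ph$volume$fat)$right,
       water = split_and_flip(ph$volume$water)$right,
       mask = split_and_flip(ph$truth$breast_mask_right$data)$right)
}

combined_truth <- function(truth) {
  pmin(truth$breast_mask_right$data + truth$breast_mask_left$data, 1)
}

combined_pred <- function(res) {
  pmin(res$right_mask$data + res$left_mask$data, 1)
}

# independent exhaustive Otsu oracle: 256-bin between-class variance search
otsu_oracle <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  bin <- pmin(as.integer((v - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  best <- -Inf; best_t <- NA
  for (t in seq_len(nbins)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * centers[1:t]) / w0
    mu1 <- sum(p[(t + 1):nbins] * centers[(t + 1):nbins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  lo + best_t / nbins * (hi - lo)
}

# independent sums-of-squares ICC(A,1) oracle
icc_oracle <- function(x1, x2) {
  X <- cbind(x1, x2)
  n <- nrow(X); k <- 2
  grand <- mean(X)
  msr <- k * sum((rowMeans(X) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(X) - grand)^2) / (k - 1)
  sse <- sum((X - outer(rowMeans(X), rep(1, k)) -
                outer(rep(1, n), colMeans(X)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
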