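# Image-processing chain producing noise-free, right-canonicalized
# single-sided combined images: fat-water sum -> min-max normalization ->
# Canny edge enhancement -> Otsu thresholding -> morphological body mask ->
# background removal of the sigmoid-combined image -> midline split and flip.

#' Preprocessing configuration
#'
#' Parameters of the body-masking chain. Canny runs 2D per transverse slice;
#' the morphological closing uses a ball structuring element, hole filling is
#' 2D per slice, and only the largest connected foreground component is kept.
#'
#' @param canny_sigma Gaussian smoothing scale in voxels before edge detection.
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude; `canny_low < canny_high`.
#' @param closing_radius Ball structuring-element radius in voxels (>= 1).
#' @param edge_weight Weight of the edge map added to the normalized sum image
#'   (0.5: detected edge intensity is halved).
#' @param clip_enhanced Clip the edge-enhanced image back to `[0, 1]` so the
#'   Otsu histogram has a fixed domain.
#' @param sigmoid_variant `"as_printed"` uses the sigmoid decision function
#'   with exponent `(-SI_W - 0.25)/SI_F` exactly as published;
#'   `"offset_scaled"` is the alternative reading `-(SI_W - 0.25*SI_F)/SI_F`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(canny_sigma = 1.0, canny_low = 0.1,
                              canny_high = 0.2, closing_radius = 3L,
                              edge_weight = 0.5, clip_enhanced = TRUE,
                              sigmoid_variant = c("as_printed",
                                                  "offset_scaled")) {
  stopifnot(canny_low < canny_high, closing_radius >= 1)
  structure(list(canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 closing_radius = as.integer(closing_radius),
                 edge_weight = edge_weight, clip_enhanced = clip_enhanced,
                 sigmoid_variant = match.arg(sigmoid_variant)),
            class = "preprocess_config")
}

#' Min-max normalization to `[0, 1]`
#'
#' Maps the minimum to 0 and the maximum to 1. A constant volume is degenerate
#' and returns all zeros with a warning.
#'
#' @param volume Numeric array with finite values.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  if (!all(is.finite(volume))) stop("volume must be finite")
  lo <- min(volume); hi <- max(volume)
  if (hi == lo) {
    warning("constant volume: min-max normalization is degenerate, returning zeros")
    return(array(0, dim(volume)))
  }
  (volume - lo) / (hi - lo)
}

#' Fat-water-sum image
#'
#' Voxelwise sum of the fat-only and water-only signal intensities; structural
#' variation within breast and pectoral regions largely cancels, which makes
#' the whole-body support easy to mask.
#'
#' @param fw A [fat_water_volume].
#' @return 3D array `fat + water`.
#' @export
fat_water_sum <- function(fw) {
  stopifnot(inherits(fw, "fat_water_volume"))
  fw$fat + fw$water
}

#' Sigmoid decision-function combination of fat and water images
#'
#' Computes the combined image
#' `SI_C = 1 / (1 + exp((-SI_W - 0.25) / SI_F))` voxelwise, which brightens
#' water-dominant tissue (fibroglandular, pectoral muscle) against fat and
#' sharpens the breast/pectoral interface. Where `SI_F` is numerically zero
#' (below `1e-8 * max(SI_F)`) the exponent is taken to its limit: the
#' numerator is always negative for non-negative `SI_W`, so the output is 1
#' there; background voxels among these are zeroed later by the body mask.
#'
#' @param fw A [fat_water_volume].
#' @param cfg A [preprocess_config] (controls the formula variant).
#' @return 3D array with values in `(0, 1]`.
#' @export
sigmoid_combine <- function(fw, cfg = preprocess_config()) {
  stopifnot(inherits(fw, "fat_water_volume"))
  f <- fw$fat; w <- fw$water
  eps <- 1e-8 * max(f)
  num <- if (cfg$sigmoid_variant == "as_printed") {
    -w - 0.25
  } else {
    -(w - 0.25 * f)
  }
  expo <- num / pmax(f, eps)
  degenerate <- f < eps
  expo[degenerate & num < 0] <- -Inf
  expo[degenerate & num >= 0] <- Inf
  out <- 1 / (1 + exp(expo))
  array(out, dim(f))
}

#' Canny edge detection, slice-by-slice
#'
#' Classic 2D Canny (Gaussian smoothing, gradient non-maximum suppression,
#' hysteresis thresholding) applied to each transverse slice of the normalized
#' fat-water-sum image. Slices are taken along the SI axis; in-plane
#' resolution is much finer than the slice thickness, so edges are 2D.
#'
#' @param volume 3D array, normalized to `[0, 1]`.
#' @param cfg A [preprocess_config].
#' @return Binary 3D edge map.
#' @export
canny_edges <- function(volume, cfg = preprocess_config()) {
  d <- dim(volume)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    out[, , k] <- canny_slice(volume[, , k], cfg$canny_sigma,
                              cfg$canny_low, cfg$canny_high)
  }
  out
}

#' Edge-enhanced fat-water-sum image
#'
#' Adds the halved edge map to the normalized sum image; optionally clips back
#' to `[0, 1]`.
#'
#' @param norm_sum Normalized fat-water-sum array.
#' @param edges Binary edge map of the same shape.
#' @param cfg A [preprocess_config].
#' @return Edge-enhanced array.
#' @export
edge_enhance <- function(norm_sum, edges, cfg = preprocess_config()) {
  if (!identical(dim(norm_sum), dim(edges)))
    stop("norm_sum and edges shapes differ")
  out <- norm_sum + cfg$edge_weight * edges
  if (isTRUE(cfg$clip_enhanced)) out <- pmin(pmax(out, 0), 1)
  array(out, dim(norm_sum))
}

#' Otsu foreground/background threshold
#'
#' Exhaustively maximizes the between-class variance over a 256-bin histogram
#' of the volume; the foreground is everything strictly above the threshold.
#'
#' @param volume Non-constant numeric array.
#' @param nbins Number of histogram bins (256).
#' @return List with `threshold` (scalar) and `foreground` (binary array).
#' @export
otsu_threshold <- function(volume, nbins = 256L) {
  lo <- min(volume); hi <- max(volume)
  if (hi == lo) stop("degenerate histogram: constant volume")
  bin <- pmin(as.integer((volume - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t_bin <- which.max(sigma_b)   # threshold at the upper edge of bin t_bin
  thr <- lo + t_bin / nbins * (hi - lo)
  list(threshold = thr, foreground = array(as.numeric(volume > thr),
                                           dim(volume)))
}

#' Body mask from the Otsu foreground
#'
#' Morphological closing (dilation then erosion) with a ball structuring
#' element bridges gaps, per-slice hole filling removes interior cavities, and
#' only the largest connected component is retained to suppress residual noise
#' islands.
#'
#' @param foreground Binary 3D array.
#' @param cfg A [preprocess_config].
#' @return Binary body mask.
#' @export
body_mask <- function(foreground, cfg = preprocess_config()) {
  if (!all(foreground %in% c(0, 1))) stop("foreground must be binary")
  if (sum(foreground) == 0) stop("empty body region")
  offs <- ball_offsets(cfg$closing_radius)
  m <- binary_close(foreground, offs)
  m <- fill_holes_slices(m)
  largest_component(m, connectivity = 6L)
}

#' Full preprocessing pipeline
#'
#' Runs, in order: fat-water sum, min-max normalization, Canny edge detection,
#' edge enhancement, Otsu thresholding, morphological body masking, background
#' removal of the sigmoid-combined image, and the midline split with left
#' flip. The result is one right-canonical [single_breast_volume] per side.
#'
#' @param fw A [fat_water_volume].
#' @param cfg A [preprocess_config].
#' @return List with elements `right` and `left` ([single_breast_volume]s),
#'   plus `body_mask` (full-grid binary array) and `otsu_threshold`.
#' @export
preprocess_pipeline <- function(fw, cfg = preprocess_config()) {
  stopifnot(inherits(fw, "fat_water_volume"))
  s <- fat_water_sum(fw)
  ns <- minmax_normalize(s)
  edges <- canny_edges(ns, cfg)
  enh <- edge_enhance(ns, edges, cfg)
  ot <- otsu_threshold(enh)
  bm <- body_mask(ot$foreground, cfg)
  combined <- sigmoid_combine(fw, cfg) * bm
  halves_img <- split_and_flip(combined, fw$axis_labels)
  halves_bm <- split_and_flip(bm, fw$axis_labels)
  right <- single_breast_volume(halves_img$right, halves_bm$right,
                                side = "right", spacing = fw$spacing)
  left <- single_breast_volume(halves_img$left, halves_bm$left,
                               side = "left", flipped = TRUE,
                               spacing = fw$spacing)
  list(right = right, left = left, body_mask = bm,
       otsu_threshold = ot$threshold, lr_axis = halves_img$lr_axis)
}
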