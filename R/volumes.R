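# Domain containers shared by every pipeline.
#
# Arrays are plain R arrays in (x, y, z) axis order; the anatomical meaning of
# each axis is carried in `axis_labels` ("LR" left-right, "AP"
# anterior-posterior, "SI" superior-inferior) and never inferred from file
# layout. Voxel coordinates used internally are 0-based.

#' Construct a fat/water volume pair
#'
#' Bundles co-registered fat-only and water-only 3D MR volumes (the outputs of
#' a Dixon fat-water decomposition) with their voxel spacing and anatomical
#' axis labels. This is the raw input of every pipeline in the package.
#'
#' @param fat,water 3D non-negative intensity arrays of identical shape
#'   (arbitrary MR units).
#' @param spacing Voxel size `(dx, dy, dz)` in mm, strictly positive.
#' @param axis_labels Character vector naming the anatomical direction of each
#'   array axis; must be a permutation of `c("LR", "AP", "SI")`.
#' @return An object of class `fat_water_volume`.
#' @export
fat_water_volume <- function(fat, water, spacing = c(1, 1, 1),
                             axis_labels = c("LR", "AP", "SI")) {
  if (!is.array(fat) || length(dim(fat)) != 3L ||
      !is.array(water) || length(dim(water)) != 3L)
    stop("fat and water must be 3D arrays")
  if (!identical(dim(fat), dim(water)))
    stop("incompatible fat/water grids")
  if (!all(is.finite(fat)) || !all(is.finite(water)))
    stop("invalid intensity volume: non-finite values")
  if (min(fat) < 0 || min(water) < 0)
    stop("invalid intensity volume: negative intensities")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  if (length(axis_labels) != 3L || !setequal(axis_labels, c("LR", "AP", "SI")))
    stop("axis_labels must be a permutation of LR, AP, SI")
  structure(list(fat = fat, water = water, spacing = as.numeric(spacing),
                 axis_labels = axis_labels),
            class = "fat_water_volume")
}

#' Construct a single-sided processed breast volume
#'
#' A right-canonicalized half volume: the combined (sigmoid fat-water) image in
#' `[0, 1]`, the binary body mask on the same grid, and the side provenance.
#' Left-sided volumes are stored flipped so that all processing happens in a
#' single "right breast" orientation.
#'
#' @param image 3D array with values in `[0, 1]`.
#' @param body_mask 3D binary array, same shape as `image`.
#' @param side `"left"` or `"right"`.
#' @param flipped Logical; must be `TRUE` iff `side == "left"`.
#' @param spacing Voxel size in mm.
#' @return An object of class `single_breast_volume`.
#' @export
single_breast_volume <- function(image, body_mask, side = c("right", "left"),
                                 flipped = (side == "left"),
                                 spacing = c(1, 1, 1)) {
  side <- match.arg(side)
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be a 3D array")
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  if (!identical(dim(image), dim(body_mask)))
    stop("image and body_mask shapes differ")
  if (!all(body_mask %in% c(0, 1)))
    stop("body_mask must be binary")
  if (!identical(flipped, side == "left"))
    stop("flipped must be TRUE iff side == 'left'")
  structure(list(image = image, body_mask = array(as.numeric(body_mask),
                                                  dim(body_mask)),
                 side = side, flipped = flipped,
                 spacing = as.numeric(spacing)),
            class = "single_breast_volume")
}

#' Construct a binary segmentation mask
#'
#' @param data 3D array with values in `{0, 1}`.
#' @param spacing Voxel size in mm.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("mask must be binary")
  structure(list(data = array(as.numeric(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "segmentation_mask")
}

#' Construct a per-voxel breast probability map
#'
#' @param data 3D array with values in `[0, 1]`.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("probability map must be a 3D array")
  if (min(data) < 0 || max(data) > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(data = data), class = "probability_map")
}

#' Read a fat/water volume pair from NIfTI files
#'
#' Reads co-registered fat-only and water-only volumes. Small negative values
#' within numeric noise (`|v| < 1e-6 * max`) are clamped to zero; substantive
#' negatives are rejected.
#'
#' @param path_fat,path_water Paths to the fat-only and water-only NIfTI files.
#' @param axis_labels Anatomical axis assignment of the stored array axes.
#' @return A [fat_water_volume].
#' @export
read_fat_water <- function(path_fat, path_water,
                           axis_labels = c("LR", "AP", "SI")) {
  f <- read_nifti(path_fat)
  w <- read_nifti(path_water)
  if (!identical(dim(f$data), dim(w$data)))
    stop("incompatible fat/water grids")
  clamp <- function(x) {
    tol <- 1e-6 * max(abs(x))
    if (min(x) < -tol) stop("invalid intensity volume: negative intensities")
    x[x < 0] <- 0
    x
  }
  fat_water_volume(clamp(f$data), clamp(w$data), spacing = f$spacing,
                   axis_labels = axis_labels)
}

#' Write a segmentation mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit so that file round-trips are
#' bit-identical.
#'
#' @param mask A [segmentation_mask].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  write_nifti(mask$data, path, spacing = mask$spacing, datatype = "uint8")
}

#' Read a segmentation mask from NIfTI
#'
#' @param path Path to a binary mask volume.
#' @return A [segmentation_mask].
#' @export
read_mask <- function(path) {
  x <- read_nifti(path)
  segmentation_mask(x$data, spacing = x$spacing)
}

lr_axis <- function(axis_labels) {
  ax <- match("LR", axis_labels)
  if (is.na(ax)) stop("cannot locate left-right axis")
  ax
}

#' Flip an array along the left-right axis
#'
#' An involution: flipping twice returns the input.
#'
#' @param x 3D array.
#' @param axis Axis index to reverse (default 1).
#' @return The flipped array.
#' @export
flip_lr <- function(x, axis = 1L) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- dim(x)[axis]:1
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Split a bilateral volume at the midline and canonicalize orientation
#'
#' Divides a full-width array into its right and left halves along the
#' left-right axis at the fixed geometric midline, then flips the left half so
#' both outputs are in canonical right-breast orientation. For odd widths the
#' single central column is dropped from both halves, keeping them congruent.
#'
#' @param x 3D array (a full-width image or mask).
#' @param axis_labels Anatomical axis assignment (used to find the LR axis).
#' @return A list with elements `right` and `left` (both right-canonical
#'   arrays) and `lr_axis`, the axis that was split.
#' @export
split_and_flip <- function(x, axis_labels = c("LR", "AP", "SI")) {
  ax <- lr_axis(axis_labels)
  w <- dim(x)[ax]
  if (w < 2L) stop("left-right width must be at least 2")
  h <- w %/% 2L
  take <- function(ix) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[ax]] <- ix
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  right <- take(seq_len(h))
  left <- take(seq.int(w - h + 1L, w))
  list(right = right, left = flip_lr(left, ax), lr_axis = ax)
}

#' Reassemble a bilateral volume from canonical halves
#'
#' Inverse of [split_and_flip] for even widths: un-flips the left half and
#' concatenates along the left-right axis.
#'
#' @param right,left Right-canonical half arrays of identical shape.
#' @param lr_axis Axis along which to concatenate.
#' @return The merged array.
#' @export
mirror_merge <- function(right, left, lr_axis = 1L) {
  stopifnot(identical(dim(right), dim(left)))
  d <- dim(right)
  left_orig <- flip_lr(left, lr_axis)
  perm <- c(lr_axis, setdiff(1:3, lr_axis))
  r <- aperm(right, perm)
  l <- aperm(left_orig, perm)
  out <- array(0, dim = c(2L * d[lr_axis], d[perm[2]], d[perm[3]]))
  out[seq_len(d[lr_axis]), , ] <- r
  out[d[lr_axis] + seq_len(d[lr_axis]), , ] <- l
  aperm(out, order(perm))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b Binary arrays or [segmentation_mask] objects of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "segmentation_mask")) a <- a$data
  if (inherits(b, "segmentation_mask")) b <- b$data
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
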