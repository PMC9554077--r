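# Seeded synthetic fat/water breast phantoms with analytically known ground
# truth: noisy background, torso with a pectoral-muscle wedge that can "jut"
# into the breast, two breast hemispheres of controllable size, and smooth
# fibroglandular blobs occupying a controllable volume fraction. The entire
# test substrate of the package.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' The stated world of the synthetic generator. Geometry is parametric
#' (ellipsoids, a wedge, smoothed Gaussian blobs) so the true breast masks and
#' true density are known exactly; all randomness is governed by `seed`.
#'
#' @param shape Voxel grid `(nx, ny, nz)`, each >= 16; x is left-right, y is
#'   anterior-posterior (anterior at low y), z is superior-inferior.
#' @param breast_radius_range Min/max breast hemisphere radius in voxels;
#'   defaults to 10-16 voxels at the reference 64-voxel width and scales
#'   proportionally with `shape[1]`.
#' @param density_fraction Target fibroglandular volume fraction in `[0, 1]`.
#' @param muscle_jut Maximum anterior protrusion of the pectoral wedge into
#'   the breast region, in voxels (>= 0).
#' @param noise_sigma Gaussian noise SD added to both channels (MR units).
#' @param fat_level,water_level Mean tissue intensities of fat-dominant and
#'   water-dominant tissue.
#' @param spacing Voxel size in mm.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 48L),
                         breast_radius_range = NULL,
                         density_fraction = 0.3,
                         muscle_jut = 2,
                         noise_sigma = 20,
                         fat_level = 600,
                         water_level = 600,
                         spacing = c(2, 2, 2),
                         seed = 1L) {
  if (is.null(breast_radius_range))
    breast_radius_range <- c(10, 16) * shape[1] / 64
  stopifnot(length(shape) == 3L, all(shape >= 16),
            density_fraction >= 0, density_fraction <= 1,
            muscle_jut >= 0, noise_sigma >= 0,
            fat_level > 0, water_level > 0,
            length(breast_radius_range) == 2L,
            breast_radius_range[1] <= breast_radius_range[2])
  structure(list(shape = as.integer(shape),
                 breast_radius_range = breast_radius_range,
                 density_fraction = density_fraction,
                 muscle_jut = muscle_jut,
                 noise_sigma = noise_sigma,
                 fat_level = fat_level, water_level = water_level,
                 spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic geometry + seeded texture; returns everything pre-noise
build_phantom_noiseless <- function(spec) {
  d <- spec$shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cc <- grid_coords(d)
  cx <- (nx - 1) / 2; cz <- (nz - 1) / 2
  y_chest <- 0.58 * ny
  r_range <- spec$breast_radius_range
  if (r_range[2] > min(nx / 4, 0.55 * ny, nz / 2))
    stop("infeasible geometry: breast larger than grid")

  radii <- runif(2, r_range[1], r_range[2])       # right, left
  elong <- runif(2, 0.85, 1.15)                   # z-anisotropy per breast
  bx <- c(cx - nx / 4, cx + nx / 4)
  jut_sx <- nx / 6; jut_sz <- nz / 5

  torso_extent <- ((cc$x - cx) / (0.48 * nx))^2 +
    ((cc$z - cz) / (0.48 * nz))^2 <= 1
  torso <- torso_extent & cc$y > y_chest & cc$y < ny - 2
  bump <- spec$muscle_jut *
    exp(-(((cc$x - cx)^2) / (2 * jut_sx^2) + ((cc$z - cz)^2) / (2 * jut_sz^2)))
  wedge <- torso_extent & cc$y >= y_chest - bump & cc$y <= y_chest + 4 &
    cc$y < ny - 2
  torso_fat <- torso & !wedge

  breast <- vector("list", 2L)
  for (s in 1:2) {
    dist2 <- ((cc$x - bx[s]) / radii[s])^2 +
      ((cc$y - y_chest) / radii[s])^2 +
      ((cc$z - cz) / (radii[s] * elong[s]))^2
    breast[[s]] <- dist2 <= 1 & cc$y < y_chest & !wedge
    if (!any(breast[[s]])) stop("infeasible geometry: empty breast")
  }

  # fibroglandular blobs: smoothed Gaussian field thresholded per breast at
  # the quantile giving exactly the requested volume fraction
  field <- gaussian_smooth(array(rnorm(prod(d)), d), sigma = 2.5)
  fgt <- array(FALSE, d)
  for (s in 1:2) {
    idx <- which(breast[[s]])
    nk <- round(spec$density_fraction * length(idx))
    if (nk > 0) {
      ord <- order(field[idx], decreasing = TRUE)
      fgt[idx[ord[seq_len(nk)]]] <- TRUE
    }
  }

  fat <- array(0, d); water <- array(0, d)
  fat[torso_fat] <- spec$fat_level
  water[wedge] <- spec$water_level
  fat[breast[[1]] | breast[[2]]] <- spec$fat_level
  fat[fgt] <- 0
  water[fgt] <- spec$water_level

  list(fat = fat, water = water,
       breast_right = breast[[1]], breast_left = breast[[2]],
       wedge = wedge, body = torso | wedge | breast[[1]] | breast[[2]],
       fgt = fgt, texture = field)
}

add_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  pmax(x + array(rnorm(length(x), sd = sigma), dim(x)), 0)
}

true_density_of <- function(fat, water, mask_arr, spacing) {
  fw <- fat_water_volume(fat, water, spacing = spacing)
  md <- magdensity(fat_fraction(fw),
                   segmentation_mask(array(as.numeric(mask_arr), dim(fat)),
                                     spacing = spacing))
  md$magdensity
}

#' Generate a synthetic fat/water breast phantom
#'
#' Builds a bilateral phantom: low-intensity noise background,
#' a posterior torso, a water-dominant pectoral wedge protruding per
#' `muscle_jut`, two breast hemispheres anterior to the wedge, and smooth
#' fibroglandular blobs occupying `density_fraction` of each breast. Gaussian
#' noise is added to both channels and clamped at zero. Ground truth (breast
#' masks excluding the wedge, body support, true MagDensity computed pre-
#' noise) is returned alongside.
#'
#' @param spec A [phantom_spec].
#' @return List with `volume` (a [fat_water_volume]) and `truth` (class
#'   `phantom_truth`: `breast_mask_right`, `breast_mask_left`, `body_support`,
#'   `true_magdensity`, `fat_noiseless`, `water_noiseless`, `spec`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    g <- build_phantom_noiseless(spec)
    d <- spec$shape
    breast_all <- g$breast_right | g$breast_left
    true_md <- true_density_of(g$fat, g$water, breast_all, spec$spacing)
    fat <- add_noise(g$fat, spec$noise_sigma)
    water <- add_noise(g$water, spec$noise_sigma)
    truth <- structure(list(
      breast_mask_right = segmentation_mask(array(as.numeric(g$breast_right), d),
                                            spacing = spec$spacing),
      breast_mask_left = segmentation_mask(array(as.numeric(g$breast_left), d),
                                           spacing = spec$spacing),
      body_support = array(as.numeric(g$body), d),
      true_magdensity = true_md,
      fat_noiseless = g$fat, water_noiseless = g$water,
      spec = spec), class = "phantom_truth")
    list(volume = fat_water_volume(fat, water, spacing = spec$spacing),
         truth = truth)
  })
}

smooth_random_field <- function(d, scale, sigma = 10) {
  if (scale <= 0) return(lapply(1:3, function(i) array(0, d)))
  u <- lapply(1:3, function(i) gaussian_smooth(array(rnorm(prod(d)), d), sigma))
  mx <- max(sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2))   # max vector magnitude
  lapply(u, function(x) x / mx * scale)
}

#' Generate a synthetic test-retest phantom pair
#'
#' Emulates back-to-back scans of the same subject: the second scan's anatomy
#' is the first phantom's label geometry warped by a smooth random
#' low-amplitude deformation; tissue intensities are repainted from the
#' deformed labels (no interpolation mixing, so tissue composition is
#' preserved) and an independent noise realization is added. Truth masks are
#' warped through the same field and the second true MagDensity is recomputed
#' from the deformed geometry.
#'
#' @param spec A [phantom_spec].
#' @param deform_scale Maximum displacement magnitude of the inter-scan
#'   deformation in voxels (small relative to the breast radius; default 2).
#' @return List with elements `first` and `second`, each a
#'   `list(volume, truth)` as returned by [make_phantom].
#' @export
make_test_retest_pair <- function(spec = phantom_spec(), deform_scale = 2) {
  stopifnot(inherits(spec, "phantom_spec"), deform_scale >= 0)
  first <- make_phantom(spec)
  g <- with_seed(spec$seed, build_phantom_noiseless(spec))
  d <- spec$shape
  with_seed(spec$seed + 500000L, {
    u <- smooth_random_field(d, deform_scale)
    cc <- grid_coords(d)
    xs <- cc$x + u[[1]]; ys <- cc$y + u[[2]]; zs <- cc$z + u[[3]]
    warp_nn <- function(v) {
      array(cpp_nearest(as.numeric(v), as.integer(d),
                        as.numeric(xs), as.numeric(ys),
                        as.numeric(zs), 0) != 0, d)
    }
    torso_fat2 <- warp_nn(g$body & !g$wedge & !(g$breast_right | g$breast_left))
    wedge2 <- warp_nn(g$wedge)
    bR2 <- warp_nn(g$breast_right)
    bL2 <- warp_nn(g$breast_left)
    # same subject, same tissue: deform the fibroglandular texture field and
    # re-threshold at each breast's original volume fraction, so the true
    # density of the pair differs only by voxel quantization
    tex2 <- sample_trilinear(g$texture, xs, ys, zs, clamp = TRUE)
    fgt2 <- array(FALSE, d)
    for (side in list(list(b1 = g$breast_right, b2 = bR2),
                      list(b1 = g$breast_left, b2 = bL2))) {
      frac1 <- sum(g$fgt & side$b1) / max(sum(side$b1), 1)
      idx <- which(side$b2)
      nk <- round(frac1 * length(idx))
      if (nk > 0) {
        ord <- order(tex2[idx], decreasing = TRUE)
        fgt2[idx[ord[seq_len(nk)]]] <- TRUE
      }
    }
    fat2 <- array(0, d); water2 <- array(0, d)
    fat2[torso_fat2 | bR2 | bL2] <- spec$fat_level
    water2[wedge2] <- spec$water_level
    fat2[fgt2] <- 0
    water2[fgt2] <- spec$water_level
    md2 <- true_density_of(fat2, water2, bR2 | bL2, spec$spacing)
    truth2 <- structure(list(
      breast_mask_right = segmentation_mask(array(as.numeric(bR2), d),
                                            spacing = spec$spacing),
      breast_mask_left = segmentation_mask(array(as.numeric(bL2), d),
                                           spacing = spec$spacing),
      body_support = array(as.numeric(torso_fat2 | wedge2 | bR2 | bL2), d),
      true_magdensity = md2,
      fat_noiseless = fat2, water_noiseless = water2,
      spec = spec), class = "phantom_truth")
    vol2 <- fat_water_volume(add_noise(fat2, spec$noise_sigma),
                             add_noise(water2, spec$noise_sigma),
                             spacing = spec$spacing)
    list(first = first, second = list(volume = vol2, truth = truth2))
  })
}

#' Generate a phantom template dictionary
#'
#' Builds `n` single-sided template pairs spanning randomized breast sizes,
#' shapes, juts, and densities. Each phantom is run through the same
#' preprocessing canonicalization applied to targets; the template mask is the
#' phantom's ground-truth right-breast mask in the canonical half grid.
#'
#' @param n Number of templates (>= 5, the pipeline selects the top 5).
#' @param base_spec A [phantom_spec] supplying grid, intensities, and the
#'   master seed.
#' @param pre_cfg The [preprocess_config] used for canonicalization.
#' @return A [template_dictionary] of `n` pairs.
#' @export
make_dictionary <- function(n = 15L, base_spec = phantom_spec(),
                            pre_cfg = preprocess_config()) {
  if (n < 5) stop("dictionary needs at least 5 templates")
  draws <- with_seed(base_spec$seed + 900000L, {
    data.frame(r_lo = runif(n, base_spec$breast_radius_range[1],
                            mean(base_spec$breast_radius_range)),
               width = runif(n, 1, 4),
               dens = runif(n, 0.10, 0.50),
               jut = runif(n, 0, 3))
  })
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(shape = base_spec$shape,
                       breast_radius_range = c(draws$r_lo[i],
                                               pmin(draws$r_lo[i] + draws$width[i],
                                                    base_spec$breast_radius_range[2])),
                       density_fraction = draws$dens[i],
                       muscle_jut = draws$jut[i],
                       noise_sigma = base_spec$noise_sigma,
                       fat_level = base_spec$fat_level,
                       water_level = base_spec$water_level,
                       spacing = base_spec$spacing,
                       seed = base_spec$seed + 1000L + 13L * i)
    ph <- make_phantom(sp)
    pre <- preprocess_pipeline(ph$volume, pre_cfg)
    mask_half <- split_and_flip(ph$truth$breast_mask_right$data)$right
    pairs[[i]] <- template_pair(
      id = sprintf("tpl%03d", i),
      image = pre$right,
      mask = segmentation_mask(mask_half, spacing = sp$spacing),
      meta = list(density_fraction = draws$dens[i],
                  muscle_jut = draws$jut[i]))
  }
  template_dictionary(pairs)
}
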