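# Registration breast segmentation: NMI template ranking, multi-resolution
# cubic B-spline free-form-deformation registration driven by a Parzen-window
# NMI gradient, nearest-neighbour mask warping, and majority-vote fusion.

#' Registration configuration
#'
#' Parameters of the reference registration backend: a multi-resolution cubic
#' B-spline free-form deformation optimized by gradient ascent on normalized
#' mutual information with a bending-energy penalty on the control lattice.
#'
#' @param pyramid_levels Number of resolution levels (>= 1); each coarser
#'   level halves the grid.
#' @param control_point_spacing Control-point spacing in mm at the finest
#'   level (default 10 mm, i.e. 5 voxels at a 2 mm grid).
#' @param regularization_weight Bending-energy weight (>= 0).
#' @param max_iterations Gradient-ascent iterations per level.
#' @param nmi_bins Histogram bins per axis for NMI (>= 8; default 64).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(pyramid_levels = 3L,
                                control_point_spacing = 10,
                                regularization_weight = 0.001,
                                max_iterations = 40L,
                                nmi_bins = 64L) {
  stopifnot(pyramid_levels >= 1, control_point_spacing > 0,
            regularization_weight >= 0, max_iterations >= 1, nmi_bins >= 8)
  structure(list(metric = "NMI",
                 pyramid_levels = as.integer(pyramid_levels),
                 control_point_spacing = control_point_spacing,
                 regularization_weight = regularization_weight,
                 max_iterations = as.integer(max_iterations),
                 nmi_bins = as.integer(nmi_bins)),
            class = "registration_config")
}

#' Normalized mutual information between two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` estimated from a joint histogram with
#' `bins` equal-width bins per axis over each array's own `[min, max]` range.
#' Lies in `[1, 2]`; equals 2 for identical non-constant arrays.
#'
#' @param a,b Numeric arrays of identical shape, non-constant.
#' @param bins Number of histogram bins per axis.
#' @return Scalar NMI value.
#' @export
nmi <- function(a, b, bins = 64L) {
  if (!identical(dim(a), dim(b))) stop("arrays must have identical shape")
  if (min(a) == max(a) || min(b) == max(b))
    stop("constant array: NMI undefined")
  bin_of <- function(x) {
    pmin(as.integer((x - min(x)) / (max(x) - min(x)) * bins), bins - 1L)
  }
  ba <- bin_of(a); bb <- bin_of(b)
  joint <- tabulate(ba * bins + bb + 1L, bins * bins)
  p <- joint / sum(joint)
  pj <- p[p > 0]
  pa <- rowSums(matrix(p, bins, bins, byrow = TRUE))
  pb <- rowSums(matrix(p, bins, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (ent(pa) + ent(pb)) / ent(pj)
}

#' Construct a deformation field
#'
#' Per-voxel displacement (in voxel units, on the target grid) mapping target
#' coordinates to template coordinates: `x_template = x_target + u(x_target)`.
#'
#' @param ux,uy,uz Displacement component arrays on the target grid.
#' @param spacing Voxel size in mm of the target grid.
#' @param template_shape Grid shape of the template the field maps into
#'   (defaults to the target shape).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(ux, uy, uz, spacing = c(1, 1, 1),
                              template_shape = dim(ux)) {
  stopifnot(identical(dim(ux), dim(uy)), identical(dim(ux), dim(uz)),
            all(is.finite(ux)), all(is.finite(uy)), all(is.finite(uz)))
  structure(list(ux = ux, uy = uy, uz = uz, shape = dim(ux),
                 template_shape = template_shape,
                 spacing = as.numeric(spacing)),
            class = "deformation_field")
}

# ---- internal FFD machinery -------------------------------------------------

# cubic B-spline blending weights for fractional position u in [0,1)
bspline_w <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# dense basis matrix: rows = sample coords (0-based, finest-voxel units),
# cols = control points with spacing s
bspline_basis <- function(coords, s, nc) {
  i <- pmin(floor(coords / s), nc - 4L)
  u <- coords / s - i
  W <- bspline_w(u)
  B <- matrix(0, length(coords), nc)
  for (o in 0:3) B[cbind(seq_along(coords), i + o + 1L)] <- W[, o + 1L]
  B
}

mode_mult <- function(A, M, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:3, mode))
  Ap <- aperm(A, perm)
  R <- M %*% matrix(Ap, nrow = d[mode])
  aperm(array(R, c(nrow(M), d[perm[2]], d[perm[3]])), order(perm))
}

ffd_eval <- function(theta, Bx, By, Bz) {
  mode_mult(mode_mult(mode_mult(theta, Bx, 1L), By, 2L), Bz, 3L)
}

ffd_adjoint <- function(field, Bx, By, Bz) {
  mode_mult(mode_mult(mode_mult(field, t(Bx), 1L), t(By), 2L), t(Bz), 3L)
}

second_diff_matrix <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
}

bending_penalty <- function(theta, Ds) {
  val <- 0
  grad <- array(0, dim(theta))
  for (ax in 1:3) {
    D <- Ds[[ax]]
    if (nrow(D) == 0L) next
    dd <- mode_mult(theta, D, ax)
    val <- val + sum(dd^2)
    grad <- grad + 2 * mode_mult(dd, t(D), ax)
  }
  list(value = val, grad = grad)
}

# block-mean downsample by integer factor f along all axes
downsample_mean <- function(x, f) {
  if (f == 1L) return(x)
  pool_mat <- function(n) {
    g <- ceiling(n / f)
    P <- matrix(0, g, n)
    for (i in seq_len(g)) {
      idx <- ((i - 1L) * f + 1L):min(i * f, n)
      P[i, idx] <- 1 / length(idx)
    }
    P
  }
  d <- dim(x)
  mode_mult(mode_mult(mode_mult(x, pool_mat(d[1]), 1L),
                      pool_mat(d[2]), 2L), pool_mat(d[3]), 3L)
}

central_gradient <- function(x, axis) {
  n <- dim(x)[axis]
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  g <- array(0, dim(xp))
  if (n >= 3L)
    g[2:(n - 1L), , ] <- (xp[3:n, , , drop = FALSE] -
                            xp[1:(n - 2L), , , drop = FALSE]) / 2
  aperm(g, order(perm))
}

grid_coords <- function(d) {
  list(x = array(rep(0:(d[1] - 1L), times = d[2] * d[3]), d),
       y = array(rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]), d),
       z = array(rep(0:(d[3] - 1L), each = d[1] * d[2]), d))
}

sample_trilinear <- function(vol, xs, ys, zs, background = 0,
                             clamp = FALSE) {
  if (clamp) {
    d <- dim(vol)
    xs <- pmin(pmax(xs, 0), d[1] - 1)
    ys <- pmin(pmax(ys, 0), d[2] - 1)
    zs <- pmin(pmax(zs, 0), d[3] - 1)
  }
  array(cpp_trilinear(as.numeric(vol), as.integer(dim(vol)),
                      as.numeric(xs), as.numeric(ys), as.numeric(zs),
                      background), dim(xs))
}

#' Non-rigid B-spline registration of a template onto a target
#'
#' Reference backend: a center-of-mass translation initialization followed by
#' multi-resolution gradient ascent of Parzen-window NMI over a cubic B-spline
#' free-form deformation with a bending-energy penalty. The returned field
#' maps target voxel coordinates into the template grid. If the optimized
#' field would decrease full-resolution NMI relative to the unregistered
#' pair, the identity field is returned with a warning flag (the metric-
#' improvement guarantee).
#'
#' @param template_img,target_img [single_breast_volume]s in canonical
#'   orientation. Shapes may differ; the template is sampled in its own grid.
#' @param cfg A [registration_config].
#' @return A [deformation_field] with attributes `nmi_before`, `nmi_after`,
#'   and `converged`.
#' @export
register_nonrigid <- function(template_img, target_img,
                              cfg = registration_config()) {
  stopifnot(inherits(template_img, "single_breast_volume"),
            inherits(target_img, "single_breast_volume"))
  tpl_orig <- template_img$image
  tgt <- target_img$image
  if (min(tpl_orig) == max(tpl_orig) || min(tgt) == max(tgt))
    stop("degenerate (constant) image: cannot register")
  nbins <- cfg$nmi_bins
  d <- dim(tgt)
  spacing <- target_img$spacing

  # differently shaped templates are resampled onto the target grid; the
  # axis scaling is composed back into the returned field at the end
  sf <- (dim(tpl_orig) - 1) / pmax(d - 1, 1)
  if (identical(dim(tpl_orig), d)) {
    tpl <- tpl_orig
  } else {
    cc0 <- grid_coords(d)
    tpl <- sample_trilinear(tpl_orig, cc0$x * sf[1], cc0$y * sf[2],
                            cc0$z * sf[3], clamp = TRUE)
  }

  com <- function(x) {
    cc <- grid_coords(dim(x))
    s <- sum(x)
    c(sum(x * cc$x), sum(x * cc$y), sum(x * cc$z)) / s
  }
  t0 <- com(tpl) - com(tgt)

  # control lattice on the finest target grid
  s_vox <- pmax(2, cfg$control_point_spacing / spacing)
  nc <- floor((d - 1) / s_vox) + 4L
  theta <- list(array(0, nc), array(0, nc), array(0, nc))
  Ds <- lapply(1:3, function(ax) second_diff_matrix(nc[ax]))
  lam <- cfg$regularization_weight

  # consistent Parzen estimator for the optimization metric and the final
  # improvement safeguard (hard-binned nmi() is biased against interpolation
  # smoothing and would veto genuinely better alignments)
  fbin_full <- pmin(as.integer(pmax(pmin(tgt, 1), 0) * nbins), nbins - 1L)
  parzen_nmi_of <- function(img) {
    cpp_nmi_parzen(fbin_full, as.numeric(pmax(pmin(img, 1), 0)) *
                     (nbins - 1L), nbins, FALSE)$nmi
  }
  nmi_before <- parzen_nmi_of(tpl)

  # translation init: keep the centre-of-mass shift only if it actually
  # improves the metric (it can be fooled by content clipped at the grid edge)
  ccf <- grid_coords(d)
  if (any(t0 != 0)) {
    shifted <- sample_trilinear(tpl, ccf$x + t0[1], ccf$y + t0[2],
                                ccf$z + t0[3], clamp = TRUE)
    if (parzen_nmi_of(shifted) <= nmi_before) t0 <- c(0, 0, 0)
  }

  for (lev in seq_len(cfg$pyramid_levels)) {
    f <- 2L^(cfg$pyramid_levels - lev)
    tgt_l <- downsample_mean(tgt, f)
    tpl_l <- downsample_mean(tpl, f)
    dl <- dim(tgt_l)
    bins_l <- if (f > 1L) max(16L, nbins %/% f) else nbins
    fbin <- pmin(as.integer(pmax(pmin(tgt_l, 1), 0) * bins_l), bins_l - 1L)
    gx <- central_gradient(tpl_l, 1L)
    gy <- central_gradient(tpl_l, 2L)
    gz <- central_gradient(tpl_l, 3L)
    cc <- grid_coords(dl)
    # coarse voxel centers expressed in finest-voxel units
    coord_f <- function(ix, n_f) pmin(ix * f + (f - 1) / 2, n_f - 1)
    Bx <- bspline_basis(coord_f(0:(dl[1] - 1L), d[1]), s_vox[1], nc[1])
    By <- bspline_basis(coord_f(0:(dl[2] - 1L), d[2]), s_vox[2], nc[2])
    Bz <- bspline_basis(coord_f(0:(dl[3] - 1L), d[3]), s_vox[3], nc[3])
    tpl_dims <- dim(tpl_l)

    warp_coords <- function(th) {
      ux <- (t0[1] + ffd_eval(th[[1]], Bx, By, Bz)) / f
      uy <- (t0[2] + ffd_eval(th[[2]], Bx, By, Bz)) / f
      uz <- (t0[3] + ffd_eval(th[[3]], Bx, By, Bz)) / f
      list(x = cc$x + ux, y = cc$y + uy, z = cc$z + uz)
    }
    objective <- function(th, want_grad = FALSE) {
      w <- warp_coords(th)
      warped <- sample_trilinear(tpl_l, w$x, w$y, w$z, clamp = TRUE)
      res <- cpp_nmi_parzen(fbin, as.numeric(pmax(pmin(warped, 1), 0)) *
                              (bins_l - 1L), bins_l, want_grad)
      bendv <- 0; bendg <- NULL
      if (lam > 0) {
        bp <- lapply(th, bending_penalty, Ds = Ds)
        ncp <- prod(nc)   # normalize so lam is grid-size independent
        bendv <- sum(vapply(bp, `[[`, numeric(1), "value")) / ncp
        bendg <- lapply(bp, function(x) x$grad / ncp)
      }
      out <- list(value = res$nmi - lam * bendv, nmi = res$nmi)
      if (want_grad) {
        dm <- array(res$grad, dl) * (bins_l - 1L) / f
        grads <- list()
        for (ax in 1:3) {
          gvol <- switch(ax, gx, gy, gz)
          gs <- sample_trilinear(gvol, w$x, w$y, w$z, clamp = TRUE)
          G <- ffd_adjoint(dm * gs, Bx, By, Bz)
          if (lam > 0) G <- G - lam * bendg[[ax]]
          grads[[ax]] <- G
        }
        out$grads <- grads
      }
      out
    }

    step <- 2.0
    cur <- objective(theta, want_grad = TRUE)
    for (it in seq_len(cfg$max_iterations)) {
      ginf <- max(abs(unlist(cur$grads)))
      if (ginf == 0) break
      prop <- lapply(1:3, function(ax) theta[[ax]] + step * cur$grads[[ax]] / ginf)
      trial <- objective(prop, want_grad = FALSE)
      if (trial$value > cur$value) {
        theta <- prop
        cur <- objective(theta, want_grad = TRUE)
        step <- min(step * 1.5, 5)
      } else {
        step <- step * 0.4
      }
      if (step < 0.01) break
    }
  }

  # total displacement on the finest target grid
  Bx <- bspline_basis(0:(d[1] - 1L), s_vox[1], nc[1])
  By <- bspline_basis(0:(d[2] - 1L), s_vox[2], nc[2])
  Bz <- bspline_basis(0:(d[3] - 1L), s_vox[3], nc[3])
  ux <- t0[1] + ffd_eval(theta[[1]], Bx, By, Bz)
  uy <- t0[2] + ffd_eval(theta[[2]], Bx, By, Bz)
  uz <- t0[3] + ffd_eval(theta[[3]], Bx, By, Bz)
  warped <- sample_trilinear(tpl, ccf$x + ux, ccf$y + uy, ccf$z + uz,
                             clamp = TRUE)
  nmi_after <- parzen_nmi_of(warped)
  converged <- TRUE
  if (nmi_after < nmi_before) {
    # optimized field would hurt the metric: fall back to identity
    if (max(abs(ux), abs(uy), abs(uz)) > 0.5)
      warning("registration did not improve NMI; returning identity field")
    ux[] <- 0; uy[] <- 0; uz[] <- 0
    nmi_after <- nmi_before
    converged <- FALSE
  }
  # compose the template-grid scaling: x_tpl = sf * (x_tgt + u)
  if (!identical(dim(tpl_orig), d)) {
    ux <- sf[1] * (ccf$x + ux) - ccf$x
    uy <- sf[2] * (ccf$y + uy) - ccf$y
    uz <- sf[3] * (ccf$z + uz) - ccf$z
  }
  field <- deformation_field(ux, uy, uz, spacing = spacing,
                             template_shape = dim(tpl_orig))
  attr(field, "nmi_before") <- nmi_before
  attr(field, "nmi_after") <- nmi_after
  attr(field, "converged") <- converged
  field
}

#' Warp a template mask through a deformation field
#'
#' Resamples the mask with nearest-neighbour interpolation at the deformed
#' coordinates, preserving binarity without a second threshold choice.
#'
#' @param mask A [segmentation_mask] on the template grid.
#' @param field A [deformation_field] on the target grid.
#' @return A binary [segmentation_mask] on the target grid.
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "segmentation_mask"),
            inherits(field, "deformation_field"))
  if (!identical(dim(mask$data), as.integer(field$template_shape)) &&
      !identical(dim(mask$data), field$template_shape))
    stop("mask grid does not match the field's template grid")
  cc <- grid_coords(field$shape)
  vals <- cpp_nearest(as.numeric(mask$data), as.integer(dim(mask$data)),
                      as.numeric(cc$x + field$ux),
                      as.numeric(cc$y + field$uy),
                      as.numeric(cc$z + field$uz), 0)
  segmentation_mask(array(as.numeric(vals != 0), field$shape),
                    spacing = field$spacing)
}

#' Majority-vote label fusion
#'
#' A voxel enters the fused segmentation iff it is contained in at least
#' `min_votes` of the input masks (default 4 of 5).
#'
#' @param masks Non-empty list of [segmentation_mask]s on identical grids.
#' @param min_votes Minimum vote count, `1 <= min_votes <= length(masks)`.
#' @return The fused [segmentation_mask].
#' @export
vote_fusion <- function(masks, min_votes = 4L) {
  if (length(masks) == 0) stop("empty mask list")
  stopifnot(min_votes >= 1, min_votes <= length(masks))
  d <- dim(masks[[1]]$data)
  counts <- array(0, d)
  for (m in masks) {
    stopifnot(inherits(m, "segmentation_mask"))
    if (!identical(dim(m$data), d)) stop("mask grids differ")
    counts <- counts + m$data
  }
  segmentation_mask(array(as.numeric(counts >= min_votes), d),
                    spacing = masks[[1]]$spacing)
}

#' Rank dictionary templates by NMI with a target
#'
#' Returns the ids of the `k` templates whose images achieve the highest NMI
#' with the target image, in descending order; ties are broken by dictionary
#' insertion order so that test-retest runs are deterministic.
#'
#' @param target A [single_breast_volume].
#' @param dict A [template_dictionary] with at least `k` pairs.
#' @param k Number of templates to select (default 5).
#' @param bins NMI histogram bins.
#' @return Character vector of `k` template ids.
#' @export
select_templates <- function(target, dict, k = 5L, bins = 64L) {
  stopifnot(inherits(target, "single_breast_volume"),
            inherits(dict, "template_dictionary"))
  if (length(dict) < k) stop("dictionary smaller than k")
  vals <- vapply(dict$pairs, function(p) {
    img <- p$image$image
    if (!identical(dim(img), dim(target$image)))
      stop("template '", p$id, "' shape differs from target")
    nmi(target$image, img, bins)
  }, numeric(1))
  ord <- order(-vals, seq_along(vals))
  ids <- dict_ids(dict)[ord[seq_len(k)]]
  attr(ids, "nmi") <- vals[ord[seq_len(k)]]
  ids
}

embed_half <- function(half, full_dim, lr_axis, side) {
  w <- full_dim[lr_axis]
  perm <- c(lr_axis, setdiff(1:3, lr_axis))
  hp <- aperm(if (side == "right") half else flip_lr(half, lr_axis), perm)
  h <- dim(hp)[1]
  out <- array(0, c(w, dim(hp)[2], dim(hp)[3]))
  ix <- if (side == "right") seq_len(h) else seq.int(w - h + 1L, w)
  out[ix, , ] <- hp
  aperm(out, order(perm))
}

#' Registration breast segmentation pipeline
#'
#' The full pipeline: preprocessing, per-side NMI template selection (top 5),
#' non-rigid registration of each selected template, mask warping, 4-of-5
#' majority-vote fusion, and restriction to the body mask. The left mask is
#' returned in the original (un-flipped) frame; both masks are embedded in
#' the full bilateral grid.
#'
#' @param fw A [fat_water_volume].
#' @param dict A [template_dictionary] with at least `k` pairs.
#' @param pre_cfg A [preprocess_config].
#' @param reg_cfg A [registration_config].
#' @param k Number of templates to select per side.
#' @param min_votes Vote threshold for fusion.
#' @return List with `right_mask` and `left_mask` ([segmentation_mask]s on the
#'   full grid) and `report` (selected ids and NMI values per side).
#' @export
segment_registration <- function(fw, dict, pre_cfg = preprocess_config(),
                                 reg_cfg = registration_config(),
                                 k = 5L, min_votes = 4L) {
  stopifnot(inherits(fw, "fat_water_volume"))
  pre <- preprocess_pipeline(fw, pre_cfg)
  full_dim <- dim(fw$fat)
  report <- list()
  out <- list()
  for (side in c("right", "left")) {
    sbv <- pre[[side]]
    ids <- select_templates(sbv, dict, k = k, bins = reg_cfg$nmi_bins)
    warped <- list()
    for (id in ids) {
      tplp <- get_template(dict, id)
      fld <- register_nonrigid(tplp$image, sbv, reg_cfg)
      warped[[id]] <- warp_mask(tplp$mask, fld)
    }
    fused <- vote_fusion(unname(warped), min_votes = min_votes)
    fused$data <- fused$data * sbv$body_mask
    full <- embed_half(fused$data, full_dim, pre$lr_axis, side)
    out[[paste0(side, "_mask")]] <- segmentation_mask(full,
                                                      spacing = fw$spacing)
    report[[side]] <- list(template_ids = as.character(ids),
                           nmi = as.numeric(attr(ids, "nmi")),
                           dice_vs_final = vapply(warped, dice_coefficient,
                                                  numeric(1), b = fused))
  }
  c(out, list(report = report))
}
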