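## Deterministic generators for every test input: smooth synthetic intensity
## volumes (sums of anisotropic Gaussian blobs plus a smooth bias and
## optional noise), ground-truth B-spline warps with known fields, and
## synthetic Voronoi label atlases. Identical specs give bit-identical
## fixtures (all randomness flows through one seeded stream per generator
## call).

#' Specify a synthetic fixture
#'
#' @param shape Image extents per axis (>= 8 each).
#' @param spacing Voxel sizes (mm), default 1.
#' @param seed Integer seed; identical specs give identical fixtures.
#' @param n_blobs Number of Gaussian blobs in the intensity model.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units, on the [0, 1000] scale), default 0.
#' @param warp_spacing Control-point spacing (mm) of the ground-truth
#'   B-spline warp (default 4 voxels).
#' @param warp_max_disp Maximum control-point displacement (mm) of the warp;
#'   must stay below half the warp grid spacing so the warp is invertible.
#' @param n_regions Number of Voronoi regions in the label model.
#' @return A `vxfixturespec`.
#' @export
vx_fixture_spec <- function(shape, spacing = rep(1, length(shape)), seed = 1L,
                            n_blobs = 80L, noise_sd = 0,
                            warp_spacing = 4 * min(spacing),
                            warp_max_disp = 0.4 * warp_spacing,
                            n_regions = 8L) {
  if (any(shape < 8)) vx_stop("vx_contract_error", "shape must be >= 8 per axis")
  if (warp_max_disp >= 0.5 * warp_spacing)
    vx_stop("vx_contract_error",
            "warp_max_disp must be below half the warp grid spacing (invertibility)")
  structure(list(shape = as.integer(shape),
                 spacing = rep(as.double(spacing), length.out = length(shape)),
                 seed = as.integer(seed), n_blobs = as.integer(n_blobs),
                 noise_sd = as.double(noise_sd),
                 warp_spacing = as.double(warp_spacing),
                 warp_max_disp = as.double(warp_max_disp),
                 n_regions = as.integer(n_regions)),
            class = "vxfixturespec")
}

#' Generate a smooth synthetic intensity image
#'
#' A sum of `n_blobs` randomly placed anisotropic Gaussian blobs plus a
#' gentle linear bias, rescaled to `[0, 1000]`, plus optional i.i.d. Gaussian
#' noise. Deterministic given the spec.
#'
#' @param spec A [vx_fixture_spec()].
#' @return A `vximage`.
#' @export
vx_make_image <- function(spec) {
  d <- length(spec$shape)
  geom <- vx_geometry(spec$shape, spacing = spec$spacing)
  ext <- (spec$shape - 1) * spec$spacing
  vx_with_stream(spec$seed, 101L, {
    axes <- lapply(seq_len(d), function(ax) (0:(spec$shape[ax] - 1)) * spec$spacing[ax])
    arr <- array(0, spec$shape)
    for (b in seq_len(spec$n_blobs)) {
      cen <- vapply(seq_len(d), function(ax) runif(1, 0.05, 0.95) * ext[ax], 0)
      sd <- vapply(seq_len(d), function(ax) runif(1, 0.03, 0.10) * ext[ax], 0)
      amp <- runif(1, 40, 100) * sample(c(-1, 1), 1)
      parts <- lapply(seq_len(d), function(ax)
        exp(-(axes[[ax]] - cen[ax])^2 / (2 * sd[ax]^2)))
      blob <- parts[[1]]
      for (ax in 2:d) blob <- outer(blob, parts[[ax]])
      arr <- arr + amp * blob
    }
    grad <- vapply(seq_len(d), function(ax) runif(1, -1, 1), 0)
    bias <- axes[[1]] * grad[1]
    for (ax in 2:d) bias <- outer(bias, axes[[ax]] * grad[ax], `+`)
    arr <- arr + 0.02 * max(arr) * bias / max(abs(bias))
    rng <- range(arr)
    arr <- 1000 * (arr - rng[1]) / (rng[2] - rng[1])
    if (spec$noise_sd > 0)
      arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim(arr))
    vx_image(arr, geom$origin, geom$spacing, geom$direction, domain_id = "fixed")
  })
}

# random B-spline warp over a geometry; coefficients uniform in
# [-max_disp, max_disp], tapered to zero at the lattice border so the
# displacement vanishes smoothly toward the domain edge
vx_random_warp <- function(geometry, spacing_mm, max_disp, seed, stream = 202L) {
  d <- length(geometry$shape)
  tr <- vx_bspline_for_domain(geometry, spacing_mm)
  gs <- tr$grid$shape
  vx_with_stream(seed, stream, {
    coef <- array(runif(prod(gs) * d, -max_disp, max_disp), c(gs, d))
    for (ax in seq_len(d)) {
      ramp <- pmin(pmin(seq_len(gs[ax]) - 1, gs[ax] - seq_len(gs[ax])) / 2, 1)
      shp <- rep(1, d + 1); shp[ax] <- gs[ax]
      coef <- coef * array(rep(ramp, each = prod(gs[seq_len(ax - 1)])),
                           dim(coef))
    }
    tr$coefficients <- coef
    tr
  })
}

#' Generate a fixed/moving pair with known ground-truth warp
#'
#' Draws a smooth random B-spline warp `U` (fixed -> moving convention: the
#' transform a registration of `moving` onto `fixed` should recover), builds
#' the moving image as the fixed image resampled through the numerical
#' inverse of `U` (so that `I_moving(U(x)) = I_fixed(x)` up to interpolation),
#' and returns both images, the true transform, and its dense displacement
#' field on the fixed grid.
#'
#' @param spec A [vx_fixture_spec()].
#' @return List with `fixed`, `moving` (`vximage`s), `true_transform`
#'   (B-spline `vxtransform`), `true_field` (array `c(shape, d)` of mm
#'   displacements on the fixed grid).
#' @export
vx_make_warped_pair <- function(spec) {
  fixed <- vx_make_image(spec)
  geom <- vx_geometry_of(fixed)
  d <- length(spec$shape)
  U <- vx_random_warp(geom, spec$warp_spacing, spec$warp_max_disp, spec$seed)
  if (spec$warp_max_disp > 0) {
    Vinv <- vx_invert_transform(U, geom, tolerance = 1e-3, max_iter = 200L)
    moving <- vx_resample(fixed, Vinv, geom, interpolator = "bspline3")
  } else {
    moving <- fixed
  }
  moving$domain_id <- "moving"
  pts <- vx_grid_points(geom)
  tf <- vx_map_point(U, pts) - pts
  list(fixed = fixed, moving = moving, true_transform = U,
       true_field = array(tf, c(spec$shape, d)))
}

#' Generate a synthetic multi-atlas set
#'
#' Builds a base Voronoi labeling (labels `0 .. n_regions-1` from random
#' region seeds) and a matching intensity image, then produces `count`
#' atlases by warping both through small random B-spline warps (zero warp
#' amplitude gives identical atlases). Labels are propagated with
#' nearest-neighbor interpolation.
#'
#' @param spec A [vx_fixture_spec()].
#' @param count Number of atlases.
#' @param warp_amplitude Max control-point displacement (mm) of the
#'   inter-atlas warps (default `spec$warp_max_disp / 2`).
#' @return List with `base_labels` (`vxlabelimage`), `base_image`
#'   (`vximage`), and `atlases`: a list of `list(image, labels, warp)`.
#' @export
vx_make_label_atlas <- function(spec, count, warp_amplitude = spec$warp_max_disp / 2) {
  stopifnot(count >= 1, spec$n_regions >= 2)
  d <- length(spec$shape)
  geom <- vx_geometry(spec$shape, spacing = spec$spacing)
  base_image <- vx_make_image(spec)
  base_labels <- vx_with_stream(spec$seed, 303L, {
    seeds <- matrix(0, spec$n_regions, d)
    for (ax in seq_len(d))
      seeds[, ax] <- runif(spec$n_regions, 0, (spec$shape[ax] - 1) * spec$spacing[ax])
    pts <- vx_grid_points(geom)
    best <- rep(Inf, nrow(pts)); lab <- integer(nrow(pts))
    for (r in seq_len(spec$n_regions)) {
      d2 <- rowSums(sweep(pts, 2, seeds[r, ])^2)
      take <- d2 < best
      lab[take] <- r - 1L                     # labels 0 .. R-1
      best[take] <- d2[take]
    }
    vx_label_image(array(lab, spec$shape), geom$origin, geom$spacing,
                   geom$direction)
  })
  atlases <- vector("list", count)
  for (a in seq_len(count)) {
    if (warp_amplitude > 0) {
      W <- vx_random_warp(geom, spec$warp_spacing, warp_amplitude,
                          spec$seed, stream = 400L + a)
      img <- vx_resample(base_image, W, geom, "linear")
      lab_img <- vx_resample(vx_image(base_labels$data + 0, geom$origin,
                                      geom$spacing, geom$direction),
                             W, geom, "nearest")
      labs <- vx_label_image(lab_img$data, geom$origin, geom$spacing,
                             geom$direction)
    } else {
      W <- vx_identity_transform(d)
      img <- base_image
      labs <- base_labels
    }
    atlases[[a]] <- list(image = img, labels = labs, warp = W)
  }
  list(base_labels = base_labels, base_image = base_image, atlases = atlases)
}
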