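# Shared in-code fixtures; everything is generated deterministically.

# small smooth 2-d test image with texture everywhere
small_image_2d <- function(seed = 10, shape = c(32, 32)) {
  vx_make_image(vx_fixture_spec(shape, seed = seed, n_blobs = 20L,
                                warp_spacing = 8, warp_max_disp = 1))
}

# random B-spline transform over a geometry, mild amplitude
random_bspline <- function(geometry, spacing_mm = 8, amp = 0.8, seed = 4,
                           order = 3L) {
  tr <- vx_bspline_for_domain(geometry, spacing_mm, order = order)
  set.seed(seed)
  tr$coefficients[] <- runif(length(tr$coefficients), -amp, amp)
  tr
}

# brute-force dense parameter Jacobian by central differences of map_point
fd_parameter_jacobian <- function(transform, point, h = 1e-5) {
  mu <- vx_parameters(transform)
  d <- transform$dim
  J <- matrix(0, d, length(mu))
  for (j in seq_along(mu)) {
    mp <- mu; mp[j] <- mp[j] + h
    mm <- mu; mm[j] <- mm[j] - h
    J[, j] <- (vx_map_point(vx_set_parameters(transform, mp), point) -
                 vx_map_point(vx_set_parameters(transform, mm), point)) / (2 * h)
  }
  J
}

# central-ellipsoid analysis mask (synthetic stand-in for a brain mask)
ellipsoid_mask <- function(geometry, radius_frac = 0.45) {
  pts <- voxreg:::vx_grid_points(geometry)
  cen <- (geometry$shape - 1) / 2 * geometry$spacing
  r <- radius_frac * (geometry$shape - 1) * geometry$spacing
  inside <- rowSums(sweep(sweep(pts, 2, cen), 2, r, "/")^2) <= 1
  vx_label_image(array(as.integer(inside), geometry$shape),
                 geometry$origin, geometry$spacing, geometry$direction)
}

# displacement field of a transform on a geometry's voxel grid
field_of <- function(transform, geometry) {
  pts <- voxreg:::vx_grid_points(geometry)
  array(vx_map_point(transform, pts) - pts,
        c(geometry$shape, length(geometry$shape)))
}
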