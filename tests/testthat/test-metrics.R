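test_that("sample sets are deterministic, in-domain and mask-respecting", {
  img <- small_image_2d()
  s1 <- vx_draw_samples(img, NULL, 2000, seed = 3, iteration = 7)
  s2 <- vx_draw_samples(img, NULL, 2000, seed = 3, iteration = 7)
  expect_identical(s1$points, s2$points)
  expect_equal(nrow(s1$points), 2000)
  expect_equal(s1$eta * nrow(s1$points), 1)
  expect_true(all(voxreg:::vx_inside_domain(vx_geometry_of(img), s1$points)))
  s3 <- vx_draw_samples(img, NULL, 2000, seed = 3, iteration = 8)
  expect_false(identical(s1$points, s3$points))  # new set each iteration
  # mask covering the left half
  g <- vx_geometry_of(img)
  half <- vx_label_image(array(as.integer(voxreg:::vx_grid_points(g)[, 1] <
                                            (g$shape[1] - 1) / 2), g$shape))
  sm <- vx_draw_samples(img, half, 1000, seed = 4)
  expect_true(all(sm$points[, 1] < (g$shape[1] - 1) / 2 + 0.5))
  empty <- vx_label_image(array(0L, g$shape))
  expect_error(vx_draw_samples(img, empty, 10, 1), class = "vx_degenerate_error")
})

test_that("perfect alignment puts every metric at its optimum", {
  img <- small_image_2d()
  samples <- vx_draw_samples(img, NULL, 500, seed = 5)
  ip <- vx_interpolator(img, "linear")
  id <- vx_identity_transform(2)
  msd <- vx_metric_value_and_derivative("msd", img, ip, id, samples)
  expect_equal(msd$value, 0)
  expect_true(all(msd$derivative == 0))
  nc <- vx_metric_value_and_derivative("nc", img, ip, id, samples)
  expect_equal(nc$value, 0, tolerance = 1e-12)
  # NC is invariant to affine intensity maps of the moving image
  mov2 <- img; mov2$data <- 2 * img$data + 5
  nc2 <- vx_metric_value_and_derivative("nc", img, vx_interpolator(mov2, "linear"),
                                        id, samples)
  expect_equal(nc2$value, 0, tolerance = 1e-12)
  # MI at self-alignment is (numerically) a local optimum: tiny derivative
  # relative to a misaligned state
  mi0 <- vx_metric_value_and_derivative("mi", img, ip, id, samples)
  mi1 <- vx_metric_value_and_derivative("mi", img, ip, vx_translation(c(3, 0)), samples)
  expect_lt(mi0$value, mi1$value)
})

test_that("analytic metric derivatives match central finite differences", {
  # 2-d 32^2 fixture with a 6x6-ish B-spline grid, fixed sample set
  fixed <- small_image_2d(seed = 30)
  moving <- small_image_2d(seed = 31)
  bs <- random_bspline(vx_geometry_of(fixed), 8, 0.8, seed = 32)
  mip <- vx_interpolator(moving, "bspline3")
  samples <- vx_draw_samples(fixed, NULL, 400, seed = 7)
  h <- 1e-4
  for (metric in c("msd", "nc", "mi")) {
    report <- vx_metric_value_and_derivative(metric, fixed, mip, bs, samples)
    g <- report$derivative
    mu <- vx_parameters(bs)
    idx <- order(-abs(g))[1:25]
    for (j in idx) {
      mp <- mu; mp[j] <- mp[j] + h
      mm <- mu; mm[j] <- mm[j] - h
      fd <- (vx_metric_value_and_derivative(metric, fixed, mip,
                                            vx_set_parameters(bs, mp), samples)$value -
             vx_metric_value_and_derivative(metric, fixed, mip,
                                            vx_set_parameters(bs, mm), samples)$value) / (2 * h)
      expect_lt(abs(fd - g[j]) / max(abs(g[j]), 1e-3 * max(abs(g))), 1e-4)
    }
  }
})

test_that("derivatives also differentiate linear transform kinds correctly", {
  fixed <- small_image_2d(seed = 33)
  moving <- small_image_2d(seed = 34)
  mip <- vx_interpolator(moving, "bspline3")
  samples <- vx_draw_samples(fixed, NULL, 300, seed = 8)
  h <- 1e-5
  trs <- list(vx_translation(c(0.5, -0.3)),
              vx_similarity(0.05, c(0.5, 0), scale = 1.02, center = c(15, 15)),
              vx_affine(matrix(c(1.02, 0.03, -0.02, 0.98), 2, 2), c(0.3, 0.1),
                        center = c(15, 15)))
  for (tr in trs) {
    rep_ <- vx_metric_value_and_derivative("msd", fixed, mip, tr, samples)
    mu <- vx_parameters(tr)
    for (j in seq_along(mu)) {
      mp <- mu; mp[j] <- mp[j] + h
      mm <- mu; mm[j] <- mm[j] - h
      fd <- (vx_metric_value_and_derivative("msd", fixed, mip,
                                            vx_set_parameters(tr, mp), samples)$value -
             vx_metric_value_and_derivative("msd", fixed, mip,
                                            vx_set_parameters(tr, mm), samples)$value) / (2 * h)
      expect_lt(abs(fd - rep_$derivative[j]) / max(abs(rep_$derivative)), 1e-4)
    }
  }
})

test_that("out-of-domain samples are excluded and eta recomputed", {
  fixed <- small_image_2d(seed = 35)
  moving <- small_image_2d(seed = 36)
  mip <- vx_interpolator(moving, "linear")
  samples <- vx_draw_samples(fixed, NULL, 500, seed = 9)
  # translate far enough that some (but not all) samples leave the domain
  rep_ <- vx_metric_value_and_derivative("msd", fixed, mip,
                                         vx_translation(c(10, 0)), samples)
  expect_lt(rep_$samples_used, 500)
  expect_gt(rep_$samples_used, 2)
  # all samples outside -> degenerate overlap error
  expect_error(vx_metric_value_and_derivative("msd", fixed, mip,
                                              vx_translation(c(1000, 0)), samples),
               class = "vx_overlap_error")
})

test_that("bending energy annihilates affine displacements and passes FD", {
  g <- vx_geometry(c(32, 32))
  samples <- vx_draw_samples(vx_image(array(0, c(32, 32))), NULL, 300, seed = 10)
  # zero coefficients
  be0 <- vx_bending_energy_value_and_derivative(vx_bspline_for_domain(g, 8), samples)
  expect_equal(be0$value, 0)
  # coefficients encoding an exact affine displacement
  bsA <- vx_bspline_for_domain(g, 8)
  gp <- voxreg:::vx_grid_points(bsA$grid)
  A <- matrix(c(0.05, 0.02, -0.01, 0.03), 2, 2)
  bsA$coefficients <- array(sweep(gp %*% t(A), 2, c(1, -2), "+"),
                            c(bsA$grid$shape, 2))
  beA <- vx_bending_energy_value_and_derivative(bsA, samples)
  expect_lt(beA$value, 1e-10)
  expect_lt(max(abs(beA$derivative)), 1e-10)
  # finite differences on random coefficients
  bsB <- random_bspline(g, 8, 0.5, seed = 37)
  beB <- vx_bending_energy_value_and_derivative(bsB, samples)
  mu <- vx_parameters(bsB)
  h <- 1e-5
  for (j in order(-abs(beB$derivative))[1:15]) {
    mp <- mu; mp[j] <- mp[j] + h
    mm <- mu; mm[j] <- mm[j] - h
    fd <- (vx_bending_energy_value_and_derivative(vx_set_parameters(bsB, mp), samples)$value -
           vx_bending_energy_value_and_derivative(vx_set_parameters(bsB, mm), samples)$value) / (2 * h)
    expect_lt(abs(fd - beB$derivative[j]) / abs(beB$derivative[j]), 1e-4)
  }
  expect_error(vx_bending_energy_value_and_derivative(vx_translation(c(0, 0)), samples),
               class = "vx_unsupported_error")
})

test_that("partitioned evaluation is partition-count invariant", {
  fixed <- small_image_2d(seed = 38)
  moving <- small_image_2d(seed = 39)
  bs <- random_bspline(vx_geometry_of(fixed), 8, 0.8, seed = 40)
  mip <- vx_interpolator(moving, "linear")
  samples <- vx_draw_samples(fixed, NULL, 2000, seed = 11)
  r1 <- vx_evaluate_partitioned("msd", fixed, mip, bs, samples, partitions = 1)
  rA <- vx_metric_value_and_derivative("msd", fixed, mip, bs, samples)
  expect_identical(r1$derivative, rA$derivative)   # T = 1 is the reference
  expect_identical(r1$value, rA$value)
  for (T in c(2, 8)) {
    rT <- vx_evaluate_partitioned("msd", fixed, mip, bs, samples, partitions = T)
    # reassociation bound, mixed tolerance: 1e-12 relative per component or
    # 1e-12 of the max-norm for components at rounding level
    d <- abs(rT$derivative - r1$derivative)
    expect_true(all(d <= 1e-12 * abs(r1$derivative) |
                      d <= 1e-12 * max(abs(r1$derivative))))
    sizes <- vapply(attr(rT, "partials"), function(p) p$samples_in_partition, 0)
    expect_lte(diff(range(sizes)), 1)              # sizes differ by at most 1
    expect_equal(sum(sizes), rT$samples_used)
  }
  expect_error(vx_evaluate_partitioned("msd", fixed, mip, bs, samples,
                                       partitions = 3000),
               class = "vx_contract_error")
})

test_that("join_partials is a count-weighted eta sum", {
  p1 <- structure(list(values = c(1, 2, 3), thread_id = 1L,
                       samples_in_partition = 10L), class = "vxpartialderivative")
  p2 <- structure(list(values = c(1, 2, 3), thread_id = 2L,
                       samples_in_partition = 10L), class = "vxpartialderivative")
  # two equal partials of equal weight reproduce the same mean vector
  expect_equal(vx_join_partials(list(p1, p2), 1 / 20), c(1, 2, 3))
  # single partial: values times its weight normalization
  expect_equal(vx_join_partials(list(p1), 1 / 10), c(1, 2, 3))
  # random split equals unsplit sum
  set.seed(41)
  v <- rnorm(50)
  cut1 <- v[1:20]; cut2 <- v[21:50]
  q1 <- structure(list(values = colMeans(matrix(cut1, 20, 1)) * 0 + mean(cut1),
                       thread_id = 1L, samples_in_partition = 20L),
                  class = "vxpartialderivative")
  q2 <- structure(list(values = mean(cut2), thread_id = 2L,
                       samples_in_partition = 30L), class = "vxpartialderivative")
  expect_equal(vx_join_partials(list(q1, q2), 1 / 50), mean(v), tolerance = 1e-12)
  p_bad <- structure(list(values = c(1, 2), thread_id = 3L,
                          samples_in_partition = 5L), class = "vxpartialderivative")
  expect_error(vx_join_partials(list(p1, p_bad), 1), class = "vx_contract_error")
})

test_that("sparse metric assembly equals a dense-Jacobian oracle on small N", {
  fixed <- small_image_2d(seed = 42, shape = c(24, 24))
  moving <- small_image_2d(seed = 43, shape = c(24, 24))
  bs <- random_bspline(vx_geometry_of(fixed), 10, 0.8, seed = 44)
  mip <- vx_interpolator(moving, "linear")
  samples <- vx_draw_samples(fixed, NULL, 100, seed = 12)
  rep_ <- vx_metric_value_and_derivative("msd", fixed, mip, bs, samples)
  # dense oracle: loop samples, dense J, accumulate 2(m-f) J^T grad
  fip <- vx_interpolator(fixed, "linear")
  mapped <- vx_map_point(bs, samples$points)
  inc <- which(vx_interp_inside(mip, mapped))
  acc <- numeric(length(vx_parameters(bs)))
  for (i in inc) {
    f <- vx_evaluate(fip, samples$points[i, ])
    m <- vx_evaluate(mip, mapped[i, ])
    gr <- vx_evaluate_gradient(mip, mapped[i, ])
    J <- vx_dense_parameter_jacobian(vx_parameter_jacobian(bs, samples$points[i, ]))
    acc <- acc + 2 * (m - f) * as.vector(crossprod(J, gr))
  }
  acc <- acc / length(inc)
  expect_lt(max(abs(acc - rep_$derivative)), 1e-10 * max(1, max(abs(acc))))
})

test_that("MI internals: joint histogram marginals sum to one", {
  fixed <- small_image_2d(seed = 45)
  moving <- small_image_2d(seed = 46)
  samples <- vx_draw_samples(fixed, NULL, 500, seed = 13)
  # reconstruct the histogram through the exported surface: value of -MI for
  # identical images is -(entropy), and marginal mass must be 1 by partition
  # of unity; verify via the internal weight helper
  prep <- voxreg:::vx_metric_prepare(fixed, vx_interpolator(moving, "linear"),
                                     vx_identity_transform(2), samples)
  ir <- list(fixed = range(fixed$data), moving = range(moving$data))
  mw <- voxreg:::vx_metric_weights("mi", prep$f, prep$m, 1 / prep$n_inc, 32L, ir)
  expect_true(is.finite(mw$value))
  # direct histogram check
  B <- 32L; pad <- 2L
  bwf <- (ir$fixed[2] - ir$fixed[1]) / (B - 4)
  bwm <- (ir$moving[2] - ir$moving[1]) / (B - 4)
  tf <- pmin(pmax((prep$f - ir$fixed[1]) / bwf + pad, pad), B - pad - 1e-7)
  tm <- pmin(pmax((prep$m - ir$moving[1]) / bwm + pad, pad), B - pad - 1e-7)
  W4 <- voxreg:::vx_bsp_axis_weights(tm - floor(tm), 3L, 0L)
  expect_lt(max(abs(rowSums(W4) - 1)), 1e-10)    # moving window mass
})
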