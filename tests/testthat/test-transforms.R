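test_that("map_point handles the elementary kinds", {
  expect_equal(vx_map_point(vx_translation(c(1, 2, 3)), c(0, 0, 0)), c(1, 2, 3))
  bs <- vx_bspline_for_domain(vx_geometry(c(16, 16)), 4)
  p <- matrix(runif(40, 0, 15), 20, 2)
  expect_identical(vx_map_point(bs, p), p)     # zero coefficients = identity
  # composite applies members first-to-last
  co <- vx_composite(list(vx_translation(c(1, 0, 0)), vx_affine(2 * diag(3))))
  expect_equal(vx_map_point(co, c(0, 0, 0)), c(2, 0, 0))
})

test_that("composite mapping equals the left fold of member mappings bit-exactly", {
  set.seed(5)
  g <- vx_geometry(c(20, 20))
  members <- list(vx_similarity(0.2, c(1, -1), scale = 1.1, center = c(9, 9)),
                  vx_affine(matrix(c(1.05, 0.1, -0.05, 0.95), 2, 2), c(0.5, 0)),
                  random_bspline(g, 6, 0.6, seed = 6))
  co <- vx_composite(members)
  pts <- matrix(runif(60, 2, 17), 30, 2)
  manual <- pts
  for (m in members) manual <- vx_map_point(m, manual)
  expect_identical(vx_map_point(co, pts), manual)
})

test_that("sparse parameter Jacobian matches brute-force dense differentiation", {
  set.seed(7)
  # B-spline: d x dP block structure, P = (O+1)^d
  g2 <- vx_geometry(c(24, 24))
  bs <- random_bspline(g2, 8, 0.8, seed = 8)
  jac <- vx_parameter_jacobian(bs, c(11.2, 12.7))
  expect_equal(ncol(jac$values), 16)           # (3+1)^2
  expect_equal(sum(jac$values[1, ]), 1, tolerance = 1e-10)
  J <- vx_dense_parameter_jacobian(jac)
  expect_lt(max(abs(J - fd_parameter_jacobian(bs, c(11.2, 12.7)))), 1e-8)
  # 3-d support size
  g3 <- vx_geometry(c(12, 12, 12))
  bs3 <- vx_bspline_for_domain(g3, 6)
  expect_equal(ncol(vx_parameter_jacobian(bs3, c(6, 6, 6))$values), 64)
  # linear kinds: dense Jacobian in the same container
  for (tr in list(vx_translation(c(0, 0, 0)),
                  vx_rigid(c(0.2, -0.1, 0.3), c(1, 2, 3), center = c(5, 5, 5)),
                  vx_similarity(c(0.1, 0.2, -0.3), c(1, 0, -1), scale = 1.2,
                                center = c(2, 2, 2)),
                  vx_affine(matrix(c(1.1, 0.1, 0, -0.05, 0.9, 0.2, 0, 0.1, 1.05),
                                   3, 3, byrow = TRUE), c(1, -1, 2)))) {
    x0 <- c(7, 3, 2)
    J <- vx_dense_parameter_jacobian(vx_parameter_jacobian(tr, x0))
    expect_lt(max(abs(J - fd_parameter_jacobian(tr, x0, h = 1e-6))), 1e-6)
  }
  # translation Jacobian is the identity
  Jt <- vx_dense_parameter_jacobian(vx_parameter_jacobian(vx_translation(c(0, 0)), c(3, 4)))
  expect_identical(Jt, diag(2))
})

test_that("partition of unity holds at random interior points", {
  set.seed(9)
  bs <- vx_bspline_for_domain(vx_geometry(c(20, 20, 20)), 5)
  pts <- matrix(runif(300, 2, 17), 100, 3)
  for (i in seq_len(nrow(pts))) {
    jac <- vx_parameter_jacobian(bs, pts[i, ])
    expect_equal(sum(jac$values[1, ]), 1, tolerance = 1e-10)
  }
})

test_that("sparse_gradient_product equals the dense product", {
  set.seed(10)
  bs <- random_bspline(vx_geometry(c(24, 24)), 8, 0.8, seed = 11)
  for (rep in 1:20) {
    x <- runif(2, 3, 20)
    gvec <- rnorm(2)
    jac <- vx_parameter_jacobian(bs, x)
    sp <- vx_sparse_gradient_product(jac, gvec)
    dense <- as.vector(crossprod(vx_dense_parameter_jacobian(jac), gvec))
    full <- numeric(jac$n_params)
    full[sp$indices] <- sp$values
    expect_lt(max(abs(full - dense)), 1e-12)
    expect_length(sp$values, 2 * length(jac$indices))  # d * P entries
  }
  # zero gradient and translation identity cases
  jac <- vx_parameter_jacobian(bs, c(10, 10))
  expect_true(all(vx_sparse_gradient_product(jac, c(0, 0))$values == 0))
  jt <- vx_parameter_jacobian(vx_translation(c(0, 0)), c(1, 1))
  expect_equal(vx_sparse_gradient_product(jt, c(3, -2))$values, c(3, -2))
})

test_that("spatial Jacobian determinants match analytic and numeric oracles", {
  expect_equal(vx_spatial_jacobian_determinant(vx_identity_transform(3), c(1, 2, 3)), 1)
  s <- 1.3
  expect_equal(vx_spatial_jacobian_determinant(vx_affine(s * diag(3)), c(0, 0, 0)),
               s^3, tolerance = 1e-12)
  # B-spline: central finite differences of the mapping
  set.seed(12)
  bs <- random_bspline(vx_geometry(c(24, 24)), 8, 1.5, seed = 13)
  pts <- matrix(runif(20, 5, 18), 10, 2)
  dets <- vx_spatial_jacobian_determinant(bs, pts)
  h <- 1e-5
  for (i in seq_len(nrow(pts))) {
    Jn <- matrix(0, 2, 2)
    for (ax in 1:2) {
      e <- c(0, 0); e[ax] <- h
      Jn[, ax] <- (vx_map_point(bs, pts[i, ] + e) - vx_map_point(bs, pts[i, ] - e)) / (2 * h)
    }
    expect_equal(dets[i], det(Jn), tolerance = 1e-6)
  }
  # composite: chain-rule product of member determinants
  co <- vx_composite(list(vx_affine(1.2 * diag(2)), bs))
  dco <- vx_spatial_jacobian_determinant(co, pts)
  for (i in seq_len(nrow(pts))) {
    Jn <- matrix(0, 2, 2)
    for (ax in 1:2) {
      e <- c(0, 0); e[ax] <- h
      Jn[, ax] <- (vx_map_point(co, pts[i, ] + e) - vx_map_point(co, pts[i, ] - e)) / (2 * h)
    }
    expect_equal(dco[i], det(Jn), tolerance = 1e-5)
  }
})

test_that("transform averaging implements the pointwise mean with optional identity", {
  g <- vx_geometry(c(10, 10))
  pts <- voxreg:::vx_grid_points(g)
  # all identity -> identity
  U <- vx_average_transforms(list(vx_identity_transform(2), vx_identity_transform(2)), g)
  expect_lt(max(abs(vx_map_point(U, pts) - pts)), 1e-12)
  # mean of two translations
  U2 <- vx_average_transforms(list(vx_translation(c(1, 0)), vx_translation(c(3, 0))), g)
  expect_lt(max(abs(vx_map_point(U2, pts) - sweep(pts, 2, c(2, 0), "+"))), 1e-12)
  # identity included as a member: (t + 0) / 2
  U3 <- vx_average_transforms(list(vx_translation(c(2, 0))), g, include_identity = TRUE)
  expect_lt(max(abs(vx_map_point(U3, pts) - sweep(pts, 2, c(1, 0), "+"))), 1e-12)
  # singleton average reproduces the member on grid points
  set.seed(14)
  bs <- random_bspline(g, 5, 0.8, seed = 15)
  U4 <- vx_average_transforms(list(bs), g)
  expect_lt(max(abs(vx_map_point(U4, pts) - vx_map_point(bs, pts))), 1e-12)
  expect_error(vx_average_transforms(list(), g), class = "vx_contract_error")
})

test_that("numerical inversion reaches its tolerance", {
  g <- vx_geometry(c(16, 16))
  pts <- voxreg:::vx_grid_points(g)
  # translation inverts exactly
  V <- vx_invert_transform(vx_translation(c(1.5, -2)), g, tolerance = 1e-10)
  expect_lt(max(abs(vx_map_point(V, pts) - sweep(pts, 2, c(-1.5, 2), "+"))), 1e-9)
  # affine inverts to the closed form
  A <- matrix(c(1.1, 0.15, -0.1, 0.9), 2, 2); b <- c(1, -0.5)
  V2 <- vx_invert_transform(vx_affine(A, b), g, tolerance = 1e-10, max_iter = 200)
  Ainv <- solve(A)
  expected <- sweep(pts %*% t(Ainv), 2, as.double(Ainv %*% b), "-")
  expect_lt(max(abs(vx_map_point(V2, pts) - expected)), 1e-8)
  # small-amplitude B-spline: composition residual below tolerance
  set.seed(16)
  bs <- random_bspline(g, 6, 0.3 * 6 / 2, seed = 17)   # max disp 0.3 x spacing
  V3 <- vx_invert_transform(bs, g, tolerance = 1e-3, max_iter = 100)
  round_trip <- vx_map_point(bs, vx_map_point(V3, pts))
  expect_lt(max(sqrt(rowSums((round_trip - pts)^2))), 1e-3)
  expect_lt(attr(V3, "residual"), 1e-3)
})

test_that("transform serialization round-trips all kinds", {
  td <- withr::local_tempdir()
  set.seed(18)
  g <- vx_geometry(c(12, 12))
  kinds <- list(vx_translation(c(1, 2)),
                vx_rigid(0.3, c(1, -1), center = c(5, 5)),
                vx_similarity(0.2, c(0, 1), scale = 1.1, center = c(4, 4)),
                vx_affine(matrix(c(1.1, 0.1, 0, 0.9), 2, 2), c(1, 0)),
                random_bspline(g, 6, 0.7, seed = 19))
  kinds$composite <- vx_composite(kinds[c(1, 4, 5)])
  pts <- matrix(runif(40, 1, 10), 20, 2)
  for (tr in kinds) {
    p <- file.path(td, paste0(tr$kind, ".txt"))
    vx_write_transform(tr, p)
    back <- vx_read_transform(p)
    expect_lt(max(abs(vx_map_point(back, pts) - vx_map_point(tr, pts))), 1e-12)
  }
  # displacement field via vector MetaImage
  df <- vx_dfield(array(rnorm(12 * 12 * 2, 0, 0.5), c(12, 12, 2)), g)
  p <- file.path(td, "dfield.txt")
  vx_write_transform(df, p)
  back <- vx_read_transform(p)
  expect_lt(max(abs(vx_map_point(back, pts) - vx_map_point(df, pts))), 1e-12)
})
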