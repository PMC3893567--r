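## Parametric coordinate transforms T_mu: translation, rigid, similarity,
## affine, cubic B-spline free-form deformation, composition, and dense
## displacement fields. Transforms map fixed-domain physical points (mm) into
## the moving domain. Linear kinds act about an optional fixed center c:
## T(x) = M (x - c) + c + t.

vx_new_transform <- function(kind, d, fields) {
  structure(c(list(kind = kind, dim = as.integer(d)), fields),
            class = "vxtransform")
}

#' @export
print.vxtransform <- function(x, ...) {
  cat(sprintf("<vxtransform %s, %d-d, %d parameter(s)>\n",
              x$kind, x$dim, length(vx_parameters(x))))
  invisible(x)
}

#' Construct coordinate transforms
#'
#' @description
#' * `vx_translation(t)` — pure translation by `t` (mm).
#' * `vx_rigid(angles, translation, center)` — rotation (Euler angles, radians;
#'   in 3-d the rotation matrix is `Rz(az) Ry(ay) Rx(ax)` with
#'   `angles = c(ax, ay, az)`) about `center`, then translation.
#' * `vx_similarity(...)` — rigid plus one isotropic scale factor.
#' * `vx_affine(A, translation, center)` — general linear map `A` about
#'   `center`, then translation.
#' * `vx_bspline(grid_geometry, coefficients, order)` — free-form deformation:
#'   `T(x) = x + sum_i c_i j_i(x)` over the `(order+1)^d` control points whose
#'   tensor-product basis supports `x`; identity outside the grid support.
#' * `vx_composite(members)` — function composition; members are applied
#'   first-to-last, so `map(x) = T_n(... T_2(T_1(x)))`.
#' * `vx_dfield(field, geometry)` — dense displacement field sampled on a voxel
#'   grid, linearly interpolated between voxels (edge-clamped outside).
#'
#' @param t,translation Translation vector (mm).
#' @param angles Euler angle(s) in radians (length 1 in 2-d, 3 in 3-d).
#' @param center Center of rotation/scaling (mm), default the origin.
#' @param scale Isotropic scale factor.
#' @param A d x d matrix.
#' @param grid_geometry `vxgeometry` of the control-point lattice.
#' @param coefficients Array `c(grid shape, d)` of control-point displacement
#'   coefficients (mm); default all zero (identity).
#' @param order Spline order (3 = cubic, the default, or 1).
#' @param members Non-empty list of transforms sharing dimension.
#' @param field Array `c(shape, d)` of per-voxel displacements (mm).
#' @param geometry `vxgeometry` the field is sampled on.
#' @return A `vxtransform`.
#' @name vx_transforms
NULL

#' @rdname vx_transforms
#' @export
vx_translation <- function(t) {
  d <- length(t)
  vx_new_transform("translation", d, list(t = as.double(t)))
}

#' @rdname vx_transforms
#' @export
vx_rigid <- function(angles, translation = rep(0, if (length(angles) == 1) 2 else 3),
                     center = rep(0, length(translation))) {
  d <- length(translation)
  if ((d == 2 && length(angles) != 1) || (d == 3 && length(angles) != 3))
    vx_stop("vx_contract_error", "2-d rigid needs 1 angle, 3-d rigid needs 3")
  vx_new_transform("rigid", d, list(angles = as.double(angles),
                                    t = as.double(translation),
                                    center = as.double(center)))
}

#' @rdname vx_transforms
#' @export
vx_similarity <- function(angles, translation = rep(0, if (length(angles) == 1) 2 else 3),
                          scale = 1, center = rep(0, length(translation))) {
  tr <- vx_rigid(angles, translation, center)
  vx_new_transform("similarity", tr$dim,
                   list(angles = tr$angles, t = tr$t, scale = as.double(scale),
                        center = tr$center))
}

#' @rdname vx_transforms
#' @export
vx_affine <- function(A, translation = rep(0, nrow(A)),
                      center = rep(0, nrow(A))) {
  d <- nrow(A)
  stopifnot(ncol(A) == d, length(translation) == d)
  vx_new_transform("affine", d, list(A = matrix(as.double(A), d, d),
                                     t = as.double(translation),
                                     center = as.double(center)))
}

#' @rdname vx_transforms
#' @export
vx_bspline <- function(grid_geometry, coefficients = NULL, order = 3L) {
  stopifnot(inherits(grid_geometry, "vxgeometry"))
  d <- length(grid_geometry$shape)
  if (is.null(coefficients))
    coefficients <- array(0, c(grid_geometry$shape, d))
  stopifnot(all(dim(coefficients) == c(grid_geometry$shape, d)))
  vx_new_transform("bspline", d,
                   list(grid = grid_geometry,
                        coefficients = array(as.double(coefficients),
                                             dim(coefficients)),
                        order = as.integer(order)))
}

#' @rdname vx_transforms
#' @export
vx_composite <- function(members) {
  if (length(members) == 0)
    vx_stop("vx_contract_error", "composite member list must be non-empty")
  d <- members[[1]]$dim
  for (m in members)
    if (!inherits(m, "vxtransform") || m$dim != d)
      vx_stop("vx_contract_error", "composite members must share dimension")
  vx_new_transform("composite", d, list(members = members))
}

#' @rdname vx_transforms
#' @export
vx_dfield <- function(field, geometry) {
  d <- length(geometry$shape)
  stopifnot(length(dim(field)) == d + 1L, all(dim(field)[seq_len(d)] == geometry$shape),
            dim(field)[d + 1L] == d)
  vx_new_transform("dfield", d, list(field = array(as.double(field), dim(field)),
                                     geometry = geometry))
}

#' @rdname vx_transforms
#' @export
vx_identity_transform <- function(d) vx_translation(rep(0, d))

## Parameter vector access ----------------------------------------------------

# Rotation matrix and its per-angle derivatives.
vx_rotation_matrix <- function(angles, d, deriv = 0L) {
  if (d == 2) {
    th <- angles[1]
    if (deriv == 0L)
      return(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
    return(list(matrix(c(-sin(th), cos(th), -cos(th), -sin(th)), 2, 2)))
  }
  ax <- angles[1]; ay <- angles[2]; az <- angles[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  if (deriv == 0L) return(Rz %*% Ry %*% Rx)
  dRx <- matrix(c(0, 0, 0, 0, -sin(ax), cos(ax), 0, -cos(ax), -sin(ax)), 3, 3)
  dRy <- matrix(c(-sin(ay), 0, -cos(ay), 0, 0, 0, cos(ay), 0, -sin(ay)), 3, 3)
  dRz <- matrix(c(-sin(az), cos(az), 0, -cos(az), -sin(az), 0, 0, 0, 0), 3, 3)
  list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
}

#' Get or set the parameter vector of a transform
#'
#' Parameter layouts: translation `t`; rigid `(angles, t)`; similarity
#' `(angles, t, scale)`; affine `(A row-major, t)`; B-spline one block of
#' control-point coefficients per spatial component (x-block, then y-block,
#' then z-block, each in array order); composite the concatenation of its
#' members. For a composite only the last (outermost) member is optimized
#' during registration: [vx_active_parameters()] addresses that block.
#'
#' @param transform A `vxtransform`.
#' @param mu Replacement parameter vector (same length).
#' @return `vx_parameters()` a numeric vector; setters return the transform.
#' @export
vx_parameters <- function(transform) {
  switch(transform$kind,
    translation = transform$t,
    rigid = c(transform$angles, transform$t),
    similarity = c(transform$angles, transform$t, transform$scale),
    affine = c(as.vector(t(transform$A)), transform$t),
    bspline = as.vector(transform$coefficients),
    composite = unlist(lapply(transform$members, vx_parameters), use.names = FALSE),
    dfield = as.vector(transform$field),
    vx_stop("vx_contract_error", "unknown transform kind"))
}

#' @rdname vx_parameters
#' @export
vx_set_parameters <- function(transform, mu) {
  d <- transform$dim
  n0 <- length(vx_parameters(transform))
  if (length(mu) != n0)
    vx_stop("vx_contract_error", sprintf("expected %d parameters, got %d", n0, length(mu)))
  mu <- as.double(mu)
  switch(transform$kind,
    translation = { transform$t <- mu },
    rigid = {
      na <- if (d == 2) 1L else 3L
      transform$angles <- mu[seq_len(na)]
      transform$t <- mu[na + seq_len(d)]
    },
    similarity = {
      na <- if (d == 2) 1L else 3L
      transform$angles <- mu[seq_len(na)]
      transform$t <- mu[na + seq_len(d)]
      transform$scale <- mu[na + d + 1L]
    },
    affine = {
      transform$A <- matrix(mu[seq_len(d * d)], d, d, byrow = TRUE)
      transform$t <- mu[d * d + seq_len(d)]
    },
    bspline = {
      transform$coefficients <- array(mu, dim(transform$coefficients))
    },
    composite = {
      at <- 0L
      for (i in seq_along(transform$members)) {
        ni <- length(vx_parameters(transform$members[[i]]))
        transform$members[[i]] <-
          vx_set_parameters(transform$members[[i]], mu[at + seq_len(ni)])
        at <- at + ni
      }
    },
    dfield = { transform$field <- array(mu, dim(transform$field)) })
  transform
}

#' @rdname vx_parameters
#' @export
vx_active_parameters <- function(transform) {
  if (transform$kind == "composite")
    vx_parameters(transform$members[[length(transform$members)]])
  else vx_parameters(transform)
}

#' @rdname vx_parameters
#' @export
vx_set_active_parameters <- function(transform, mu) {
  if (transform$kind == "composite") {
    k <- length(transform$members)
    transform$members[[k]] <- vx_set_parameters(transform$members[[k]], mu)
    transform
  } else vx_set_parameters(transform, mu)
}

# The transform whose parameters are optimized (last member of a composite).
vx_active_transform <- function(transform) {
  if (transform$kind == "composite")
    transform$members[[length(transform$members)]]
  else transform
}

# Map points through all members except the last (identity otherwise).
vx_inner_chain_map <- function(transform, points) {
  if (transform$kind != "composite") return(points)
  k <- length(transform$members)
  if (k == 1) return(points)
  for (i in seq_len(k - 1)) points <- vx_map_point(transform$members[[i]], points)
  points
}

## Point mapping --------------------------------------------------------------

# Linear-kind matrix + offset: T(x) = M x + b.
vx_linear_matrix <- function(transform) {
  d <- transform$dim
  M <- switch(transform$kind,
    translation = diag(d),
    rigid = vx_rotation_matrix(transform$angles, d),
    similarity = transform$scale * vx_rotation_matrix(transform$angles, d),
    affine = transform$A,
    NULL)
  if (is.null(M)) return(NULL)
  cen <- if (!is.null(transform$center)) transform$center else rep(0, d)
  b <- as.double(cen + transform$t - M %*% cen)
  list(M = M, b = b)
}

# Displacement of a dfield at arbitrary points: linear interpolation with
# edge-clamped continuous indices (constant extension beyond the domain box).
vx_dfield_displacement <- function(transform, points) {
  g <- transform$geometry
  d <- length(g$shape)
  u <- vx_world_to_voxel(g, points)
  for (ax in seq_len(d)) u[, ax] <- pmin(pmax(u[, ax], 0), g$shape[ax] - 1L)
  n <- nrow(u)
  i0 <- floor(u)
  for (ax in seq_len(d)) i0[, ax] <- pmin(i0[, ax], max(g$shape[ax] - 2L, 0L))
  tfrac <- u - i0
  stride <- cumprod(c(1, g$shape[-d]))
  base <- rep(1, n)
  for (ax in seq_len(d)) base <- base + i0[, ax] * stride[ax]
  combos <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  G <- prod(g$shape)
  fld <- matrix(transform$field, G, d)
  disp <- matrix(0, n, d)
  for (p in seq_len(nrow(combos))) {
    w <- rep(1, n); off <- 0
    for (ax in seq_len(d)) {
      w <- w * if (combos[p, ax] == 0) 1 - tfrac[, ax] else tfrac[, ax]
      off <- off + combos[p, ax] * stride[ax]
    }
    idx <- as.integer(base + off)
    disp <- disp + w * fld[idx, , drop = FALSE]
  }
  disp
}

vx_bspline_displacement <- function(transform, points) {
  d <- transform$dim
  loc <- vx_bsp_locate(transform$grid, points, transform$order)
  n <- nrow(points)
  disp <- matrix(0, n, d)
  ins <- which(loc$inside)
  if (length(ins)) {
    tp <- vx_bsp_tensor(loc$i0[ins, , drop = FALSE], loc$tfrac[ins, , drop = FALSE],
                        transform$grid$shape, transform$order)
    G <- prod(transform$grid$shape)
    coef <- matrix(transform$coefficients, G, d)
    for (q in seq_len(d)) {
      cq <- coef[, q]
      vals <- matrix(cq[tp$IDX], nrow(tp$IDX), ncol(tp$IDX))
      disp[ins, q] <- rowSums(tp$W * vals)
    }
  }
  disp
}

#' Map physical points through a transform
#'
#' @param transform A `vxtransform`.
#' @param points One point (vector) or an n x d matrix of points (mm).
#' @return Mapped points, same shape as the input.
#' @export
vx_map_point <- function(transform, points) {
  d <- transform$dim
  vec_in <- is.null(dim(points))
  points <- vx_as_points(points, d)
  if (any(!is.finite(points)))
    vx_stop("vx_contract_error", "points must be finite")
  out <- switch(transform$kind,
    composite = {
      p <- points
      for (m in transform$members) p <- vx_map_point(m, p)
      p
    },
    bspline = points + vx_bspline_displacement(transform, points),
    dfield = points + vx_dfield_displacement(transform, points),
    {
      lin <- vx_linear_matrix(transform)
      vx_affine_points(points, lin$M, lin$b)
    })
  if (vec_in) as.double(out[1, ]) else out
}

## Parameter Jacobian (sparse container) --------------------------------------

#' Parameter Jacobian dT/dmu at a point
#'
#' For a B-spline transform the d x N Jacobian is block-diagonal with
#' identical rows of `P = (order+1)^d` basis products, so only those `P`
#' values plus the affected control-point indices are returned (`block =
#' TRUE`). Other kinds return their dense d x N Jacobian in the same
#' container with `block = FALSE` and `indices = 1:N`. For a composite the
#' Jacobian is taken w.r.t. the last (optimized) member, evaluated at the
#' inner-chain image of `point`.
#'
#' Use [vx_dense_parameter_jacobian()] to expand to the full d x N matrix.
#'
#' @param transform A `vxtransform`.
#' @param point A single physical point.
#' @return A list of class `vxsparsejac` with `values` (d x P matrix),
#'   `indices` (length-P column indices; for `block = TRUE` these index
#'   control points within one of the d disjoint column blocks of size `G`),
#'   `block`, `n_params`, `d`, `G`.
#' @export
vx_parameter_jacobian <- function(transform, point) {
  d <- transform$dim
  point <- vx_as_points(point, d)
  if (transform$kind == "composite") {
    inner <- vx_inner_chain_map(transform, point)
    return(vx_parameter_jacobian(vx_active_transform(transform), inner))
  }
  if (transform$kind == "bspline") {
    G <- prod(transform$grid$shape)
    loc <- vx_bsp_locate(transform$grid, point, transform$order)
    if (!loc$inside[1]) {
      return(structure(list(values = matrix(0, d, 0), indices = integer(0),
                            block = TRUE, n_params = d * G, d = d, G = G),
                       class = "vxsparsejac"))
    }
    tp <- vx_bsp_tensor(loc$i0, loc$tfrac, transform$grid$shape, transform$order)
    vals <- matrix(rep(tp$W[1, ], each = d), d, ncol(tp$W))
    return(structure(list(values = vals, indices = as.integer(tp$IDX[1, ]),
                          block = TRUE, n_params = d * G, d = d, G = G),
                     class = "vxsparsejac"))
  }
  x <- as.double(point[1, ])
  cen <- if (!is.null(transform$center)) transform$center else rep(0, d)
  xc <- x - cen
  J <- switch(transform$kind,
    translation = diag(d),
    rigid = {
      dR <- vx_rotation_matrix(transform$angles, d, deriv = 1L)
      cbind(do.call(cbind, lapply(dR, function(D) D %*% xc)), diag(d))
    },
    similarity = {
      R <- vx_rotation_matrix(transform$angles, d)
      dR <- vx_rotation_matrix(transform$angles, d, deriv = 1L)
      cbind(do.call(cbind, lapply(dR, function(D) transform$scale * (D %*% xc))),
            diag(d), R %*% xc)
    },
    affine = {
      # row-major vec(A): parameter (q-1)*d + j is A[q, j]
      J <- matrix(0, d, d * d + d)
      for (q in seq_len(d)) J[q, (q - 1) * d + seq_len(d)] <- xc
      J[, d * d + seq_len(d)] <- diag(d)
      J
    },
    vx_stop("vx_unsupported_error",
            sprintf("parameter Jacobian not defined for kind '%s'", transform$kind)))
  structure(list(values = J, indices = seq_len(ncol(J)), block = FALSE,
                 n_params = ncol(J), d = d, G = ncol(J)),
            class = "vxsparsejac")
}

#' @rdname vx_parameter_jacobian
#' @param jac A `vxsparsejac`.
#' @export
vx_dense_parameter_jacobian <- function(jac) {
  J <- matrix(0, jac$d, jac$n_params)
  if (length(jac$indices) == 0) return(J)
  if (jac$block) {
    for (q in seq_len(jac$d))
      J[q, (q - 1L) * jac$G + jac$indices] <- jac$values[q, ]
  } else {
    J[, jac$indices] <- jac$values
  }
  J
}

#' Sparse product t(J) %*% g
#'
#' Multiplies the transposed parameter Jacobian with a spatial vector (e.g.
#' the moving-image gradient), touching only the nonzero blocks: `d * P`
#' multiplications for a B-spline instead of `d * N`.
#'
#' @param jac A `vxsparsejac` from [vx_parameter_jacobian()].
#' @param image_gradient Length-d vector.
#' @return List with `values` and 1-based `indices` into the length-N
#'   parameter vector; entries not listed are zero.
#' @export
vx_sparse_gradient_product <- function(jac, image_gradient) {
  stopifnot(length(image_gradient) == jac$d)
  if (length(jac$indices) == 0)
    return(list(values = numeric(0), indices = integer(0), n_params = jac$n_params))
  if (jac$block) {
    P <- length(jac$indices)
    vals <- numeric(jac$d * P); idx <- integer(jac$d * P)
    for (q in seq_len(jac$d)) {
      vals[(q - 1L) * P + seq_len(P)] <- jac$values[q, ] * image_gradient[q]
      idx[(q - 1L) * P + seq_len(P)] <- (q - 1L) * jac$G + jac$indices
    }
    list(values = vals, indices = idx, n_params = jac$n_params)
  } else {
    list(values = as.double(crossprod(jac$values, image_gradient)),
         indices = jac$indices, n_params = jac$n_params)
  }
}

## Spatial Jacobian ------------------------------------------------------------

# n x d x d spatial Jacobians dT/dx at points.
vx_spatial_jacobian <- function(transform, points) {
  d <- transform$dim
  points <- vx_as_points(points, d)
  n <- nrow(points)
  out <- array(0, c(n, d, d))
  switch(transform$kind,
    composite = {
      # chain rule: J_total = J_k(x_{k-1}) %*% ... %*% J_1(x_0)
      acc <- array(rep(diag(d), each = n), c(n, d, d))
      p <- points
      for (m in transform$members) {
        Jm <- vx_spatial_jacobian(m, p)
        nxt <- array(0, c(n, d, d))
        for (q in seq_len(d)) for (r in seq_len(d)) {
          s <- 0
          for (l in seq_len(d)) s <- s + Jm[, q, l] * acc[, l, r]
          nxt[, q, r] <- s
        }
        acc <- nxt
        p <- vx_map_point(m, p)
      }
      out <- acc
    },
    bspline = {
      g <- transform$grid
      loc <- vx_bsp_locate(g, points, transform$order)
      for (q in seq_len(d)) out[, q, q] <- 1
      ins <- which(loc$inside)
      if (length(ins)) {
        Mchain <- solve(g$direction %*% diag(g$spacing, d))  # du/dx
        G <- prod(g$shape)
        coef <- matrix(transform$coefficients, G, d)
        i0 <- loc$i0[ins, , drop = FALSE]; tf <- loc$tfrac[ins, , drop = FALSE]
        for (ax in seq_len(d)) {
          dflags <- integer(d); dflags[ax] <- 1L
          tp <- vx_bsp_tensor(i0, tf, g$shape, transform$order, dflags)
          for (q in seq_len(d)) {
            dq_du <- rowSums(tp$W * matrix(coef[tp$IDX, q], nrow(tp$W)))
            for (r in seq_len(d))
              out[ins, q, r] <- out[ins, q, r] + dq_du * Mchain[ax, r]
          }
        }
      }
    },
    dfield = {
      # analytic derivative of the multilinear interpolant, cell-wise constant
      g <- transform$geometry
      for (q in seq_len(d)) out[, q, q] <- 1
      Mchain <- solve(g$direction %*% diag(g$spacing, d))
      u <- vx_world_to_voxel(g, points)
      for (ax in seq_len(d)) u[, ax] <- pmin(pmax(u[, ax], 0), g$shape[ax] - 1L)
      i0 <- floor(u)
      for (ax in seq_len(d)) i0[, ax] <- pmin(i0[, ax], max(g$shape[ax] - 2L, 0L))
      tfrac <- u - i0
      stride <- cumprod(c(1, g$shape[-d]))
      base <- rep(1, n)
      for (ax in seq_len(d)) base <- base + i0[, ax] * stride[ax]
      G <- prod(g$shape)
      fld <- matrix(transform$field, G, d)
      combos <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
      for (ax in seq_len(d)) {
        dd <- matrix(0, n, d)    # d(disp)/du_ax
        for (p in seq_len(nrow(combos))) {
          w <- rep(1, n); off <- 0
          for (bx in seq_len(d)) {
            wb <- if (bx == ax) {
              if (combos[p, bx] == 0) rep(-1, n) else rep(1, n)
            } else {
              if (combos[p, bx] == 0) 1 - tfrac[, bx] else tfrac[, bx]
            }
            w <- w * wb
            off <- off + combos[p, bx] * stride[bx]
          }
          idx <- as.integer(base + off)
          dd <- dd + w * fld[idx, , drop = FALSE]
        }
        for (q in seq_len(d)) for (r in seq_len(d))
          out[, q, r] <- out[, q, r] + dd[, q] * Mchain[ax, r]
      }
    },
    {
      lin <- vx_linear_matrix(transform)
      for (q in seq_len(d)) for (r in seq_len(d)) out[, q, r] <- lin$M[q, r]
    })
  out
}

#' Determinant of the spatial Jacobian dT/dx
#'
#' @param transform A `vxtransform`.
#' @param points One point or an n x d matrix.
#' @return Numeric vector of determinants, one per point.
#' @export
vx_spatial_jacobian_determinant <- function(transform, points) {
  d <- transform$dim
  points <- vx_as_points(points, d)
  J <- vx_spatial_jacobian(transform, points)
  if (d == 2) {
    J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  } else {
    J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
}

## Averaging and inversion -----------------------------------------------------

#' Average a set of transforms into a displacement field
#'
#' Computes `U(x) = (1/N) sum_j W_j(x)` pointwise on the voxel grid of
#' `geometry` and returns the result as a dense displacement-field transform
#' (linearly interpolated between voxels). This is the transformation-averaging
#' step of unbiased template construction; with `include_identity = TRUE` the
#' identity map is counted as one member of the average.
#'
#' @param transforms Non-empty list of transforms from a common domain.
#' @param geometry `vxgeometry` on which the average is sampled.
#' @param include_identity Count the identity as an extra member?
#' @return A displacement-field `vxtransform`.
#' @export
vx_average_transforms <- function(transforms, geometry, include_identity = FALSE) {
  if (length(transforms) == 0)
    vx_stop("vx_contract_error", "transform list must be non-empty")
  d <- length(geometry$shape)
  pts <- vx_grid_points(geometry)
  acc <- matrix(0, nrow(pts), d)
  for (tr in transforms) acc <- acc + vx_map_point(tr, pts)
  N <- length(transforms) + as.integer(include_identity)
  if (include_identity) acc <- acc + pts
  disp <- acc / N - pts
  vx_dfield(array(disp, c(geometry$shape, d)), geometry)
}

#' Numerically invert a transform on a voxel grid
#'
#' Finds the displacement field `V` with `U(V(x)) = x` at every voxel center
#' of `geometry` by damped fixed-point iteration `v <- v - damp * (U(x + v) -
#' x)` (damping 1, halved to 0.5 when the worst residual increases), stopping
#' when the maximum residual norm drops below `tolerance`.
#'
#' @param transform The forward transform `U` (assumed diffeomorphic on the
#'   domain).
#' @param geometry Grid on which the inverse is sampled.
#' @param tolerance Maximum allowed residual (mm), default 0.01.
#' @param max_iter Iteration cap, default 50.
#' @return A displacement-field `vxtransform` with attribute `residual` (the
#'   achieved maximum residual, mm).
#' @export
vx_invert_transform <- function(transform, geometry, tolerance = 0.01,
                                max_iter = 50L) {
  d <- length(geometry$shape)
  x <- vx_grid_points(geometry)
  v <- matrix(0, nrow(x), d)
  damp <- 1.0
  prev_worst <- Inf
  for (it in seq_len(max_iter)) {
    r <- vx_map_point(transform, x + v) - x
    worst <- sqrt(max(rowSums(r * r)))
    if (worst <= tolerance) {
      out <- vx_dfield(array(v, c(geometry$shape, d)), geometry)
      attr(out, "residual") <- worst
      return(out)
    }
    if (worst > prev_worst) damp <- 0.5
    prev_worst <- worst
    v <- v - damp * r
  }
  r <- vx_map_point(transform, x + v) - x
  norms <- sqrt(rowSums(r * r))
  worst <- max(norms)
  if (worst <= tolerance) {
    out <- vx_dfield(array(v, c(geometry$shape, d)), geometry)
    attr(out, "residual") <- worst
    return(out)
  }
  at <- which.max(norms)
  vx_stop("vx_nonconvergence_error",
          sprintf("inversion did not reach tolerance %.3g mm (worst residual %.3g mm at grid point %d)",
                  tolerance, worst, at),
          residual = worst, location = x[at, ])
}

## Serialization ---------------------------------------------------------------

#' Write or read a transform as a plain-text parameter file
#'
#' Composites write one file per member (suffix `_member<k>`) referenced from
#' the main file; displacement fields store their field in a sibling
#' vector-valued MetaImage.
#'
#' @param transform A `vxtransform`.
#' @param path Output text file.
#' @return `vx_read_transform()` returns the `vxtransform`.
#' @export
vx_write_transform <- function(transform, path) {
  lines <- c(sprintf("Kind = %s", transform$kind),
             sprintf("Dimension = %d", transform$dim))
  fmt <- function(x) paste(format(x, digits = 17), collapse = " ")
  if (transform$kind == "composite") {
    base <- sub("\\.[^.]*$", "", path)
    ext <- sub(".*(\\.[^.]*)$", "\\1", path)
    files <- character(length(transform$members))
    for (i in seq_along(transform$members)) {
      files[i] <- paste0(base, "_member", i, ext)
      vx_write_transform(transform$members[[i]], files[i])
    }
    lines <- c(lines, sprintf("MemberFiles = %s",
                              paste(basename(files), collapse = " ")))
  } else if (transform$kind == "bspline") {
    g <- transform$grid
    lines <- c(lines,
               sprintf("Order = %d", transform$order),
               sprintf("GridShape = %s", paste(g$shape, collapse = " ")),
               sprintf("GridOrigin = %s", fmt(g$origin)),
               sprintf("GridSpacing = %s", fmt(g$spacing)),
               sprintf("GridDirection = %s", fmt(as.vector(t(g$direction)))),
               sprintf("Parameters = %s", fmt(vx_parameters(transform))))
  } else if (transform$kind == "dfield") {
    fpath <- paste0(sub("\\.[^.]*$", "", path), "_field.mha")
    vx_write_field(transform$field, transform$geometry, fpath)
    lines <- c(lines, sprintf("FieldFile = %s", basename(fpath)))
  } else {
    lines <- c(lines, sprintf("Parameters = %s", fmt(vx_parameters(transform))))
    if (!is.null(transform$center))
      lines <- c(lines, sprintf("Center = %s", fmt(transform$center)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname vx_write_transform
#' @export
vx_read_transform <- function(path) {
  if (!file.exists(path))
    vx_stop("vx_io_error", sprintf("transform file not found: '%s'", path))
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  nums <- function(key) as.double(strsplit(kv[[key]], "\\s+")[[1]])
  d <- as.integer(kv$Dimension)
  kind <- kv$Kind
  if (kind == "composite") {
    files <- strsplit(kv$MemberFiles, "\\s+")[[1]]
    members <- lapply(file.path(dirname(path), files), vx_read_transform)
    return(vx_composite(members))
  }
  if (kind == "bspline") {
    shape <- as.integer(strsplit(kv$GridShape, "\\s+")[[1]])
    g <- vx_geometry(shape, nums("GridOrigin"), nums("GridSpacing"),
                     matrix(nums("GridDirection"), d, d, byrow = TRUE))
    tr <- vx_bspline(g, order = as.integer(kv$Order))
    return(vx_set_parameters(tr, nums("Parameters")))
  }
  if (kind == "dfield") {
    f <- vx_read_field(file.path(dirname(path), kv$FieldFile))
    return(vx_dfield(f$field, f$geometry))
  }
  p <- nums("Parameters")
  cen <- if (!is.null(kv$Center)) nums("Center") else rep(0, d)
  tr <- switch(kind,
    translation = vx_translation(p),
    rigid = vx_rigid(p[seq_len(if (d == 2) 1 else 3)],
                     p[(if (d == 2) 1 else 3) + seq_len(d)], cen),
    similarity = vx_similarity(p[seq_len(if (d == 2) 1 else 3)],
                               p[(if (d == 2) 1 else 3) + seq_len(d)],
                               p[length(p)], cen),
    affine = vx_affine(matrix(p[seq_len(d * d)], d, d, byrow = TRUE),
                       p[d * d + seq_len(d)], cen),
    vx_stop("vx_format_error", sprintf("unknown transform kind '%s'", kind)))
  tr
}

## B-spline grids over a physical domain ---------------------------------------

# A control-point lattice whose full-support (evaluable) region covers the
# bounding box [lo, hi] in world coordinates, with margin. Cubic support needs
# continuous grid index u in [1, shape-2]; order 1 needs [0, shape-1].
vx_bspline_grid_for_box <- function(lo, hi, spacing_mm, order = 3L) {
  d <- length(lo)
  spacing_mm <- rep(as.double(spacing_mm), length.out = d)
  pad <- if (order == 3L) 1 else 0
  origin <- lo - pad * spacing_mm
  span <- (hi - origin) / spacing_mm
  shape <- as.integer(ceiling(span + 1e-9)) + pad + 1L
  shape <- pmax(shape, order + 1L)
  vx_geometry(shape, origin, spacing_mm, diag(d))
}

#' Build a zero B-spline transform covering an image domain
#'
#' The control-point lattice is placed so that every point of the geometry's
#' voxel-center box (optionally after mapping through `inner`, the frozen
#' earlier stages of a composite) has full basis support, plus one spacing of
#' margin.
#'
#' @param geometry The fixed-image `vxgeometry` (or a `vximage`).
#' @param spacing_mm Control-point spacing (mm), scalar or per-axis.
#' @param order Spline order (3 or 1).
#' @param inner Optional transform applied to the domain before coverage is
#'   computed (for composition staging).
#' @return A `vxtransform` of kind `bspline` with zero coefficients.
#' @export
vx_bspline_for_domain <- function(geometry, spacing_mm, order = 3L, inner = NULL) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  d <- length(geometry$shape)
  corners <- as.matrix(do.call(expand.grid,
                               lapply(geometry$shape, function(s) c(0, s - 1))))
  pts <- vx_voxel_to_world(geometry, corners)
  if (!is.null(inner)) {
    # probe a lattice, not just corners: the inner stage may be nonlinear
    probe <- lapply(geometry$shape, function(s) seq(0, s - 1, length.out = 5))
    lattice <- as.matrix(do.call(expand.grid, probe))
    pts <- vx_map_point(inner, vx_voxel_to_world(geometry, lattice))
  }
  lo <- apply(pts, 2, min) - spacing_mm
  hi <- apply(pts, 2, max) + spacing_mm
  g <- vx_bspline_grid_for_box(lo, hi, spacing_mm, order)
  vx_bspline(g, order = order)
}
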