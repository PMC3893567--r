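## Image value and gradient evaluation at non-voxel positions.
## Kinds: nearest, linear, bspline1 (order-1 B-spline == linear values),
## bspline3 (cubic with recursive coefficient prefilter).
##
## Domain rule: the image domain is the closed box of voxel centers. Points
## outside it return `outside_value` (default 0); an inside predicate is
## available via vx_interp_inside(). Coefficient prefiltering and stencil
## access use mirror boundary extension.

#' Create an interpolator for an image
#'
#' @param image A `vximage`.
#' @param kind One of `"nearest"`, `"linear"`, `"bspline1"`, `"bspline3"`.
#' @param outside_value Value returned outside the image domain (default 0).
#' @return An object of class `vxinterp`.
#' @details For `bspline3` the image is prefiltered once into B-spline
#'   coefficients (recursive causal/anti-causal filter with pole
#'   `sqrt(3) - 2`, mirror boundary), so that the interpolant reproduces the
#'   voxel values at voxel centers.
#' @export
vx_interpolator <- function(image, kind = c("linear", "nearest", "bspline1", "bspline3"),
                            outside_value = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(image, "vximage"))
  coef <- NULL
  if (kind == "bspline3") coef <- vx_bspline_prefilter(image$data)
  structure(list(kind = kind, image = image,
                 geometry = vx_geometry_of(image),
                 coefficients = coef,
                 outside_value = as.double(outside_value)),
            class = "vxinterp")
}

## Cubic B-spline prefilter ----------------------------------------------------

# In-place recursive prefilter along one dimension of an array, operating on a
# matrix whose columns are the scan lines. Pole z1 = sqrt(3) - 2; gain 6.
vx_prefilter_lines <- function(m) {
  z1 <- sqrt(3) - 2
  n <- nrow(m)
  if (n == 1) return(m * 1)          # constant line: coefficient = value
  m <- m * 6
  # causal init: c+[1] = sum_{k>=0} z1^k x[mirror(1-k)]; the mirrored signal
  # has period 2n-2, so the infinite sum is one period divided by
  # (1 - z1^(2n-2)) -- exact for any line length
  per <- 2L * n - 2L
  idx <- vapply(0:(per - 1L), function(i) {
    p <- 1L - i
    p <- ((p - 1L) %% per + per) %% per + 1L
    if (p > n) p <- per - p + 2L
    p
  }, integer(1))
  w <- z1^(0:(per - 1L)) / (1 - z1^per)
  init <- as.vector(crossprod(m[idx, , drop = FALSE], w))
  cplus <- m
  cplus[1, ] <- init
  for (i in 2:n) cplus[i, ] <- m[i, ] + z1 * cplus[i - 1, ]
  # anti-causal init (mirror): c-[n] = z1/(z1^2-1) * (c+[n] + z1*c+[n-1])
  cm <- cplus
  cm[n, ] <- (z1 / (z1 * z1 - 1)) * (cplus[n, ] + z1 * cplus[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z1 * (cm[i + 1, ] - cplus[i, ])
  cm
}

# Prefilter a full array along every axis.
vx_bspline_prefilter <- function(arr) {
  dm <- dim(arr)
  d <- length(dm)
  for (ax in seq_len(d)) {
    perm <- c(ax, setdiff(seq_len(d), ax))
    a <- aperm(arr, perm)
    m <- matrix(a, dm[ax], prod(dm[-ax]))
    m <- vx_prefilter_lines(m)
    a <- array(m, dm[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

## Evaluation ------------------------------------------------------------------

# mirror-reflect 0-based continuous/integer indices into [0, n-1]
vx_mirror_index <- function(i, n) {
  if (n == 1) return(i * 0L)
  per <- 2L * (n - 1L)
  i <- ((i %% per) + per) %% per
  ifelse(i > n - 1L, per - i, i)
}

#' Inside-domain predicate of an interpolator
#'
#' @param interp A `vxinterp`.
#' @param points One point or an n x d matrix (mm).
#' @return Logical vector.
#' @export
vx_interp_inside <- function(interp, points) {
  vx_inside_domain(interp$geometry, vx_as_points(points, length(interp$geometry$shape)))
}

#' Evaluate an image at arbitrary physical points
#'
#' Applies the interpolator's rule in continuous voxel coordinates; points
#' outside the closed voxel-center box return `outside_value`.
#'
#' @param interp A `vxinterp` from [vx_interpolator()].
#' @param points One point (vector) or n x d matrix of physical points (mm).
#' @return Numeric vector of interpolated intensities.
#' @export
vx_evaluate <- function(interp, points) {
  g <- interp$geometry
  d <- length(g$shape)
  points <- vx_as_points(points, d)
  u <- vx_world_to_voxel(g, points)
  inside <- rep(TRUE, nrow(u))
  for (ax in seq_len(d))
    inside <- inside & u[, ax] >= 0 & u[, ax] <= g$shape[ax] - 1L
  out <- rep(interp$outside_value, nrow(u))
  ins <- which(inside)
  if (length(ins) == 0) return(out)
  ui <- u[ins, , drop = FALSE]
  out[ins] <- switch(interp$kind,
    nearest  = vx_eval_nearest(interp, ui),
    linear   = vx_eval_linear(interp$image$data, ui, value = TRUE)$value,
    bspline1 = vx_eval_linear(interp$image$data, ui, value = TRUE)$value,
    bspline3 = vx_eval_cubic(interp, ui, value = TRUE)$value)
  out
}

# Nearest neighbor: round half away from zero, componentwise.
vx_round_half_away <- function(x) trunc(x + sign(x) * 0.5)

vx_eval_nearest <- function(interp, u) {
  g <- interp$geometry
  d <- ncol(u)
  idx <- vx_round_half_away(u)
  for (ax in seq_len(d)) idx[, ax] <- pmin(pmax(idx[, ax], 0), g$shape[ax] - 1L)
  stride <- cumprod(c(1, g$shape[-d]))
  flat <- rep(1, nrow(u))
  for (ax in seq_len(d)) flat <- flat + idx[, ax] * stride[ax]
  as.vector(interp$image$data)[as.integer(flat)]
}

# Multilinear interpolation with optional analytic gradient (per grid unit).
# Mirror boundary for stencil access (only reachable on the domain edge).
vx_eval_linear <- function(arr, u, value = TRUE, gradient = FALSE) {
  dm <- dim(arr); d <- length(dm)
  n <- nrow(u)
  i0 <- floor(u)
  for (ax in seq_len(d)) i0[, ax] <- pmin(pmax(i0[, ax], 0), max(dm[ax] - 2L, 0L))
  tfrac <- u - i0
  stride <- cumprod(c(1, dm[-d]))
  base <- rep(1, n)
  for (ax in seq_len(d)) base <- base + i0[, ax] * stride[ax]
  combos <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  vecarr <- as.vector(arr)
  val <- if (value) numeric(n) else NULL
  grad <- if (gradient) matrix(0, n, d) else NULL
  for (p in seq_len(nrow(combos))) {
    w <- rep(1, n); off <- 0
    for (ax in seq_len(d)) {
      w <- w * if (combos[p, ax] == 0) 1 - tfrac[, ax] else tfrac[, ax]
      off <- off + combos[p, ax] * stride[ax]
    }
    v <- vecarr[as.integer(base + off)]
    if (value) val <- val + w * v
    if (gradient) for (ax in seq_len(d)) {
      wg <- if (combos[p, ax] == 0) rep(-1, n) else rep(1, n)
      for (bx in seq_len(d)) if (bx != ax)
        wg <- wg * if (combos[p, bx] == 0) 1 - tfrac[, bx] else tfrac[, bx]
      grad[, ax] <- grad[, ax] + wg * v
    }
  }
  list(value = val, grad_u = grad)
}

# Cubic B-spline evaluation from prefiltered coefficients, with optional
# gradient (per grid unit). Mirror boundary on coefficient indices.
vx_eval_cubic <- function(interp, u, value = TRUE, gradient = FALSE) {
  coefs <- interp$coefficients
  dm <- dim(coefs); d <- length(dm)
  n <- nrow(u)
  fl <- floor(u)
  tfrac <- u - fl
  i0 <- fl - 1
  stride <- cumprod(c(1, dm[-d]))
  veccoef <- as.vector(coefs)
  wl <- lapply(seq_len(d), function(ax) vx_bsp_axis_weights(tfrac[, ax], 3L, 0L))
  wl1 <- if (gradient)
    lapply(seq_len(d), function(ax) vx_bsp_axis_weights(tfrac[, ax], 3L, 1L))
  else NULL
  # mirrored per-axis absolute indices for the 4-point stencil
  midx <- lapply(seq_len(d), function(ax) {
    sapply(0:3, function(a) vx_mirror_index(i0[, ax] + a, dm[ax]))
  })
  combos <- as.matrix(do.call(expand.grid, rep(list(0:3), d)))
  val <- if (value) numeric(n) else NULL
  grad <- if (gradient) matrix(0, n, d) else NULL
  for (p in seq_len(nrow(combos))) {
    flat <- rep(1, n)
    for (ax in seq_len(d))
      flat <- flat + matrix(midx[[ax]], n)[, combos[p, ax] + 1L] * stride[ax]
    v <- veccoef[as.integer(flat)]
    if (value) {
      w <- wl[[1]][, combos[p, 1] + 1L]
      if (d > 1) for (ax in 2:d) w <- w * wl[[ax]][, combos[p, ax] + 1L]
      val <- val + w * v
    }
    if (gradient) for (ax in seq_len(d)) {
      wg <- rep(1, n)
      for (bx in seq_len(d)) {
        wb <- if (bx == ax) wl1[[bx]][, combos[p, bx] + 1L]
              else wl[[bx]][, combos[p, bx] + 1L]
        wg <- wg * wb
      }
      grad[, ax] <- grad[, ax] + wg * v
    }
  }
  list(value = val, grad_u = grad)
}

#' Evaluate the spatial image gradient at arbitrary points
#'
#' Returns the analytic spatial derivative of the interpolant, converted to
#' physical units (intensity per mm) through the image spacing and direction.
#' The linear-interpolator gradient is the fast path used by the metric
#' derivative; `bspline1` gradients coincide with it wherever both are
#' differentiable. Nearest-neighbor has no gradient.
#'
#' @inheritParams vx_evaluate
#' @return n x d matrix of gradients (a plain vector for a single point).
#' @export
vx_evaluate_gradient <- function(interp, points) {
  if (interp$kind == "nearest")
    vx_stop("vx_unsupported_error", "nearest-neighbor interpolation has no gradient")
  g <- interp$geometry
  d <- length(g$shape)
  vec_in <- is.null(dim(points))
  points <- vx_as_points(points, d)
  u <- vx_world_to_voxel(g, points)
  inside <- rep(TRUE, nrow(u))
  for (ax in seq_len(d))
    inside <- inside & u[, ax] >= 0 & u[, ax] <= g$shape[ax] - 1L
  out <- matrix(0, nrow(u), d)
  ins <- which(inside)
  if (length(ins)) {
    ui <- u[ins, , drop = FALSE]
    gr <- switch(interp$kind,
      linear   = vx_eval_linear(interp$image$data, ui, value = FALSE, gradient = TRUE)$grad_u,
      bspline1 = vx_eval_linear(interp$image$data, ui, value = FALSE, gradient = TRUE)$grad_u,
      bspline3 = vx_eval_cubic(interp, ui, value = FALSE, gradient = TRUE)$grad_u)
    # chain rule: d/dx = (du/dx)^T d/du,  du/dx = inv(D diag(s))
    Mchain <- solve(g$direction %*% diag(g$spacing, d))
    out[ins, ] <- vx_affine_points(gr, t(Mchain), rep(0, d))
  }
  if (vec_in) as.double(out[1, ]) else out
}
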