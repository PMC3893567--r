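## Uniform B-spline basis machinery shared by the B-spline transform, the
## B-spline interpolators and the bending-energy penalty. Everything is
## vectorized over point sets: weights come back as n x (O+1) per-axis
## matrices and n x P tensor-product matrices, P = (O+1)^d.

# Per-axis basis weights at fractional offsets t in [0,1).
# order 3: support offsets -1..2 around floor(u); order 1: offsets 0..1.
# deriv: 0, 1 or 2 (2 only for cubic); derivatives are w.r.t. u (grid units).
vx_bsp_axis_weights <- function(t, order, deriv = 0L) {
  n <- length(t)
  if (order == 1L) {
    if (deriv == 0L) return(cbind(1 - t, t, deparse.level = 0))
    if (deriv == 1L) return(cbind(rep(-1, n), rep(1, n), deparse.level = 0))
    vx_stop("vx_contract_error", "order-1 B-spline has no second derivative")
  }
  if (order != 3L)
    vx_stop("vx_contract_error", "only spline orders 1 and 3 are supported")
  t2 <- t * t; t3 <- t2 * t
  if (deriv == 0L) {
    cbind((1 - 3 * t + 3 * t2 - t3) / 6,
          (4 - 6 * t2 + 3 * t3) / 6,
          (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
          t3 / 6, deparse.level = 0)
  } else if (deriv == 1L) {
    cbind(-(1 - 2 * t + t2) / 2,
          (3 * t2 - 4 * t) / 2,
          (-3 * t2 + 2 * t + 1) / 2,
          t2 / 2, deparse.level = 0)
  } else if (deriv == 2L) {
    cbind(1 - t, 3 * t - 2, 1 - 3 * t, t, deparse.level = 0)
  } else vx_stop("vx_contract_error", "deriv must be 0, 1 or 2")
}

# Continuous grid coordinates of world points: list(u = n x d continuous grid
# index, i0 = n x d integer index of the first support control point,
# tfrac = n x d fractional offsets, inside = logical n (full support
# available)).
vx_bsp_locate <- function(grid_geometry, points, order = 3L) {
  d <- length(grid_geometry$shape)
  u <- vx_world_to_voxel(grid_geometry, points)
  fl <- floor(u)
  i0 <- if (order == 3L) fl - 1 else fl
  tfrac <- u - fl
  shape <- grid_geometry$shape
  inside <- rep(TRUE, nrow(u))
  for (ax in seq_len(d))
    inside <- inside & i0[, ax] >= 0 & (i0[, ax] + order) <= shape[ax] - 1
  list(u = u, i0 = i0, tfrac = tfrac, inside = inside)
}

# Tensor-product weights and control-point indices.
# dflags: per-axis derivative order (w.r.t. grid units u).
# Returns W (n x P weights) and IDX (n x P 1-based flat control-point index).
# Rows whose support is incomplete must be filtered by the caller.
vx_bsp_tensor <- function(i0, tfrac, grid_shape, order = 3L,
                          dflags = integer(length(grid_shape))) {
  d <- length(grid_shape)
  n <- nrow(i0)
  m <- order + 1L
  wl <- vector("list", d)
  for (ax in seq_len(d))
    wl[[ax]] <- vx_bsp_axis_weights(tfrac[, ax], order, dflags[ax])
  stride <- cumprod(c(1, grid_shape[-d]))
  base <- rep(1, n)
  for (ax in seq_len(d)) base <- base + i0[, ax] * stride[ax]
  combos <- as.matrix(do.call(expand.grid, rep(list(0:(m - 1L)), d)))
  P <- nrow(combos)
  W <- matrix(0, n, P); IDX <- matrix(0L, n, P)
  for (p in seq_len(P)) {
    w <- wl[[1]][, combos[p, 1] + 1L]
    off <- combos[p, 1] * stride[1]
    if (d > 1) for (ax in 2:d) {
      w <- w * wl[[ax]][, combos[p, ax] + 1L]
      off <- off + combos[p, ax] * stride[ax]
    }
    W[, p] <- w
    IDX[, p] <- as.integer(base + off)
  }
  list(W = W, IDX = IDX)
}

# Sparse accumulation: sum W[i, p] * val[i] into bins IDX[i, p] over a
# length-nbins output. The scatter core of the metric derivative.
vx_bsp_scatter <- function(W, IDX, val, nbins) {
  contrib <- as.vector(W * val)      # val recycled down columns
  idx <- as.vector(IDX)
  out <- numeric(nbins)
  s <- rowsum(contrib, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
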